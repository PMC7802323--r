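# Standard-format I/O: multi-page TIFF stacks with a JSON metadata sidecar,
# truth tables and summaries as CSV/JSON.

#' Write an image stack as multi-page TIFF with metadata sidecar
#'
#' TIFF samples are 32-bit float scaled into [0, 1] by a recorded scale
#' factor (the stack maximum by default); pixel size, scale and frame
#' count are stored in a JSON sidecar at \code{<path>.json} so the stack
#' round-trips through \code{\link{read_image_stack}} in original units
#' (to 32-bit float precision).
#'
#' @param stack numeric matrix or \code{ny x nx x n_frames} array.
#' @param path output TIFF path.
#' @param pixel_size um/pixel, recorded in the sidecar.
#' @param scale intensity scale factor; default \code{max(stack)}.
#' @return \code{path}, invisibly.
#' @export
write_image_stack <- function(stack, path, pixel_size, scale = NULL) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  scale <- scale %||% max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(t) pmin(pmax(stack[, , t] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_um = pixel_size, scale = scale,
                            n_frames = dim(stack)[3]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads frames in page order; pixel size comes from the JSON sidecar
#' written by \code{\link{write_image_stack}} or from the
#' \code{pixel_size} override. Intensities are rescaled by the sidecar
#' scale factor when present.
#'
#' @param path TIFF path.
#' @param pixel_size override um/pixel (required when no sidecar exists).
#' @return \code{ny x nx x n_frames} array with attributes
#'   \code{pixel_size_um} and \code{pixel_size_source}.
#' @export
read_image_stack <- function(path, pixel_size = NULL) {
  if (!file.exists(path))
    stop_cellmech(sprintf("no such file: %s", path), "cellmech_io_error")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop_cellmech(
                      sprintf("unreadable TIFF %s: %s", path,
                              conditionMessage(e)), "cellmech_io_error"))
  if (is.matrix(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_cellmech(sprintf(
      "ragged stack %s: page shapes differ (first mismatch at page %d)",
      path, which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]),
      "cellmech_io_error")
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  scale <- meta$scale %||% 1
  px <- pixel_size %||% meta$pixel_size_um
  if (is.null(px))
    stop_cellmech(sprintf(
      "no pixel size: %s has no metadata sidecar and no override given",
      path), "cellmech_io_error")
  stack <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (t in seq_along(pages)) stack[, , t] <- pages[[t]] * scale
  structure(stack, pixel_size_um = as.numeric(px),
            pixel_size_source = if (is.null(pixel_size)) "sidecar"
                                else "override")
}

#' Write a pillar ground-truth or deflection table as CSV
#'
#' @param table data frame (e.g. the \code{truth} table of
#'   \code{\link{simulate_pillar_sequence}} or a
#'   \code{deflection_field}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_pillar_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a cell-track table
#'
#' @param path CSV with columns \code{cell_id}, \code{t_min}, \code{x_um},
#'   \code{y_um}.
#' @return Data frame; one row per sample.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop_cellmech(sprintf("track table must have columns: %s",
                          paste(need, collapse = ", ")),
                  "cellmech_io_error")
  df
}
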