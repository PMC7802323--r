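# Reference-pillar drift correction, beam-theory forces and per-cell
# aggregation.

#' Classify reference vs under-cell pillars
#'
#' Pillars whose rest position lies outside the cell mask dilated by
#' \code{margin_um} are reference pillars (used for stage-drift
#' estimation); pillars whose rest position falls on the mask are
#' under-cell pillars. Pillars outside the mask but within the margin are
#' neither.
#'
#' @param grid a \code{\link{reconstruct_grid}} result.
#' @param cell_mask logical matrix registered to the image.
#' @param pixel_size um/pixel.
#' @param margin_um dilation margin beyond the mask (default 2 um).
#' @return Data frame: pillar_id, \code{under_cell}, distance to the mask
#'   in um (0 under the mask, Inf for an empty mask) and
#'   \code{is_reference}.
#' @export
classify_reference_pillars <- function(grid, cell_mask, pixel_size,
                                       margin_um = 2) {
  stopifnot(inherits(grid, "pillar_grid"), is.matrix(cell_mask))
  cell_mask <- cell_mask != 0
  nodes <- grid$nodes
  col <- pmin(pmax(round(nodes$rest_x_um / pixel_size) + 1, 1),
              ncol(cell_mask))
  row <- pmin(pmax(round(nodes$rest_y_um / pixel_size) + 1, 1),
              nrow(cell_mask))
  under <- cell_mask[cbind(row, col)]
  if (!any(cell_mask)) {
    dist <- rep(Inf, nrow(nodes))
  } else {
    bnd <- mask_coords_um(mask_boundary(cell_mask), pixel_size)
    dist <- vapply(seq_len(nrow(nodes)), function(k) {
      if (under[k]) return(0)
      sqrt(min((bnd[, 1] - nodes$rest_x_um[k])^2 +
               (bnd[, 2] - nodes$rest_y_um[k])^2))
    }, numeric(1))
  }
  is_ref <- !under & dist > margin_um
  if (!any(is_ref))
    stop_cellmech("no reference pillars outside the dilated cell mask; stage drift uncorrectable",
                  "cellmech_reference_error")
  data.frame(pillar_id = nodes$pillar_id, under_cell = under,
             dist_um = dist, is_reference = is_ref)
}

#' Attach reference / under-cell flags to a deflection field
#'
#' @param field a \code{\link{track_pillars}} result.
#' @param classes a \code{\link{classify_reference_pillars}} result.
#' @return The field with \code{is_reference} and \code{under_cell} columns.
#' @export
set_pillar_classes <- function(field, classes) {
  stopifnot(inherits(field, "deflection_field"))
  k <- match(field$pillar_id, classes$pillar_id)
  field$is_reference <- classes$is_reference[k]
  field$under_cell <- classes$under_cell[k]
  field
}

#' Correct stage drift with reference pillars
#'
#' Subtracts, per frame, the mean raw displacement of the tracked reference
#' pillars from every pillar's raw displacement. Any global per-frame
#' translation (stage drift) is removed exactly; by construction the mean
#' corrected displacement of the reference pillars is zero in every frame.
#'
#' @param field a \code{deflection_field} with \code{is_reference} set
#'   (see \code{\link{set_pillar_classes}}).
#' @return The field with corrected displacement columns \code{cx_um},
#'   \code{cy_um}.
#' @export
correct_drift <- function(field) {
  stopifnot(inherits(field, "deflection_field"))
  if (is.null(field$is_reference))
    stop_cellmech("is_reference flags missing; run set_pillar_classes() first",
                  "cellmech_reference_error")
  field$cx_um <- NA_real_
  field$cy_um <- NA_real_
  for (t in unique(field$frame)) {
    sel <- field$frame == t
    ref <- sel & field$is_reference & field$tracked
    if (!any(ref))
      stop_cellmech(sprintf("frame %d has no tracked reference pillars", t),
                    "cellmech_reference_error")
    field$cx_um[sel] <- field$dx_um[sel] - mean(field$dx_um[ref])
    field$cy_um[sel] <- field$dy_um[sel] - mean(field$dy_um[ref])
  }
  attr(field, "corrected") <- TRUE
  field
}

#' Convert corrected deflections to traction forces
#'
#' Force vector = stiffness times the drift-corrected displacement vector,
#' componentwise; magnitude = stiffness times displacement magnitude. The
#' stiffness comes from \code{\link{pillar_stiffness}} (beam-theory formula
#' or override; the source used is recorded on the result).
#'
#' @param field a drift-corrected \code{deflection_field} (raw
#'   displacements are used, with a warning, if \code{\link{correct_drift}}
#'   was not run — e.g. drift-free data).
#' @param geom a \code{\link{pillar_geometry}}.
#' @return The field with \code{fx_nN}, \code{fy_nN}, \code{f_mag_nN} and
#'   attributes \code{stiffness_nN_um}, \code{stiffness_source}.
#' @export
compute_forces <- function(field, geom) {
  stopifnot(inherits(field, "deflection_field"),
            inherits(geom, "pillar_geometry"))
  k <- pillar_stiffness(geom, quiet = TRUE)
  if (isTRUE(attr(field, "corrected"))) {
    dx <- field$cx_um; dy <- field$cy_um
  } else {
    warning("field is not drift-corrected; forces computed from raw displacements")
    dx <- field$dx_um; dy <- field$dy_um
  }
  field$fx_nN <- as.numeric(k) * dx
  field$fy_nN <- as.numeric(k) * dy
  field$f_mag_nN <- as.numeric(k) * sqrt(dx^2 + dy^2)
  attr(field, "stiffness_nN_um") <- as.numeric(k)
  attr(field, "stiffness_source") <- attr(k, "source")
  field
}

#' Per-cell force summary over under-cell pillars
#'
#' Per frame: number of tracked under-cell pillars, mean displacement
#' magnitude, mean force magnitude, total force as the sum of per-pillar
#' force magnitudes (a net vector sum would largely cancel for a
#' contractile cell and is reported separately), and the net vector-sum
#' magnitude. The overall summary averages the per-frame values.
#'
#' @param field a \code{deflection_field} with forces and
#'   \code{under_cell} flags.
#' @return List with \code{per_frame} (data frame) and \code{summary}
#'   (named list of across-frame means).
#' @export
aggregate_cell_forces <- function(field) {
  stopifnot(inherits(field, "deflection_field"))
  if (is.null(field$under_cell) || is.null(field$f_mag_nN))
    stop_cellmech("need under_cell flags and forces; run set_pillar_classes() and compute_forces()",
                  "cellmech_aggregate_error")
  sub <- field[field$under_cell & field$tracked, , drop = FALSE]
  if (nrow(sub) == 0)
    stop_cellmech("no tracked under-cell pillars", "cellmech_aggregate_error")
  if (isTRUE(attr(field, "corrected"))) {
    dmag <- sqrt(sub$cx_um^2 + sub$cy_um^2)
  } else {
    dmag <- sqrt(sub$dx_um^2 + sub$dy_um^2)
  }
  per_frame <- do.call(rbind, lapply(split(seq_len(nrow(sub)), sub$frame),
    function(ix) data.frame(
      frame = sub$frame[ix[1]], n_pillars = length(ix),
      mean_displacement_um = mean(dmag[ix]),
      mean_force_nN = mean(sub$f_mag_nN[ix]),
      total_force_nN = sum(sub$f_mag_nN[ix]),
      net_vector_force_nN = sqrt(sum(sub$fx_nN[ix])^2 +
                                 sum(sub$fy_nN[ix])^2))))
  rownames(per_frame) <- NULL
  list(per_frame = per_frame,
       summary = list(
         n_pillars = stats::median(per_frame$n_pillars),
         mean_displacement_um = mean(per_frame$mean_displacement_um),
         mean_force_nN = mean(per_frame$mean_force_nN),
         total_force_nN = mean(per_frame$total_force_nN),
         net_vector_force_nN = mean(per_frame$net_vector_force_nN)))
}
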