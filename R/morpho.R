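# Cell morphometry: equivalent-ellipse shape descriptors from binary masks.

#' Equivalent-ellipse shape descriptors of a cell mask
#'
#' Fits the moment-matched ellipse of a single-component binary mask: the
#' ellipse with the same area-normalized second-order central moments as
#' the mask. Axis lengths are \code{4 sqrt(lambda)} for the two eigenvalues
#' of the pixel covariance matrix (so a filled continuous ellipse recovers
#' its own axes), and the aspect ratio is major/minor.
#'
#' @param mask logical (or 0/1) matrix with exactly one connected
#'   component of at least 20 pixels.
#' @param pixel_size um/pixel.
#' @return Object of class \code{cell_shape}: \code{area_um2},
#'   \code{major_axis_um}, \code{minor_axis_um}, \code{orientation_deg}
#'   (major-axis angle from the x-axis, in (-90, 90]) and
#'   \code{aspect_ratio} (>= 1).
#' @export
fit_equivalent_ellipse <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  lab <- label_components(mask)
  n_comp <- max(lab)
  if (n_comp == 0)
    stop_cellmech("empty mask", "cellmech_mask_error")
  if (n_comp > 1)
    stop_cellmech(sprintf(
      "mask has %d connected components; split before fitting", n_comp),
      "cellmech_mask_error")
  xy <- mask_coords_um(mask, pixel_size)
  if (nrow(xy) < 20)
    stop_cellmech("mask too small (< 20 pixels) for moment fitting",
                  "cellmech_mask_error")
  mu <- colMeans(xy)
  C <- stats::cov(sweep(xy, 2, mu)) * (nrow(xy) - 1) / nrow(xy)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  major <- 4 * sqrt(lambda[1])
  minor <- 4 * sqrt(lambda[2])
  if (minor <= 0)
    stop_cellmech("degenerate mask: zero minor axis", "cellmech_mask_error")
  ang <- atan2(eig$vectors[2, 1], eig$vectors[1, 1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  structure(list(area_um2 = nrow(xy) * pixel_size^2,
                 major_axis_um = major, minor_axis_um = minor,
                 orientation_deg = ang, aspect_ratio = major / minor,
                 centroid_um = mu), class = "cell_shape")
}

#' Synthetic ellipse mask
#'
#' Rasterizes a filled ellipse (semi-axes \code{a}, \code{b} in pixels,
#' rotated by \code{angle_deg}) centred in an image; used to validate the
#' moment-based descriptors.
#'
#' @param shape image shape \code{c(ny, nx)}.
#' @param a,b semi-axes in pixels.
#' @param angle_deg rotation of the a-axis from the x-axis.
#' @return Logical matrix.
#' @export
ellipse_mask <- function(shape, a, b, angle_deg = 0) {
  cy <- (shape[1] - 1) / 2; cx <- (shape[2] - 1) / 2
  th <- angle_deg * pi / 180
  x <- matrix(rep(seq_len(shape[2]) - 1 - cx, each = shape[1]), shape[1])
  y <- matrix(rep(seq_len(shape[1]) - 1 - cy, times = shape[2]), shape[1])
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  (u / a)^2 + (v / b)^2 <= 1
}
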