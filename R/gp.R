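# Laurdan generalized polarization (GP) analysis.
#
# GP = (I420 - I473) / (I420 + I473), per pixel, in [-1, 1]; higher GP means
# a more ordered (less fluid) membrane.

#' Registered two-channel laurdan image pair
#'
#' @param I420,I473 numeric matrices of emission intensities (counts) in the
#'   420 nm and 473 nm bands; must have identical shape and be registered.
#' @param np_channel optional registered nanoparticle-channel matrix.
#' @param pixel_size optional pixel size in um/pixel.
#' @return Object of class \code{ratiometric_pair}.
#' @export
ratiometric_pair <- function(I420, I473, np_channel = NULL,
                             pixel_size = NULL) {
  stopifnot(is.matrix(I420), is.matrix(I473))
  if (!all(dim(I420) == dim(I473)))
    stop_cellmech("channel shapes differ", "cellmech_shape_error")
  if (!is.null(np_channel) && !all(dim(np_channel) == dim(I420)))
    stop_cellmech("np_channel shape differs from emission channels",
                  "cellmech_shape_error")
  if (any(I420 < 0, na.rm = TRUE) || any(I473 < 0, na.rm = TRUE))
    stop_cellmech("intensities must be >= 0", "cellmech_spec_error")
  structure(list(I420 = I420, I473 = I473, np_channel = np_channel,
                 pixel_size = pixel_size), class = "ratiometric_pair")
}

#' Compute a per-pixel GP map
#'
#' GP = (I420 - I473) / (I420 + I473) wherever the summed intensity exceeds
#' the threshold; background pixels are masked out. Without an explicit
#' threshold, Otsu's method on the sum image separates cell from background.
#'
#' @param pair a \code{\link{ratiometric_pair}}.
#' @param intensity_threshold scalar threshold on \code{I420 + I473}
#'   (counts), or \code{NULL} for an Otsu threshold of the sum image.
#' @param mask optional explicit logical mask overriding the threshold rule
#'   (still intersected with total intensity > 0).
#' @return Object of class \code{gp_map}: \code{gp} matrix (NA outside the
#'   mask), logical \code{mask}, and the threshold used.
#' @export
compute_gp_map <- function(pair, intensity_threshold = NULL, mask = NULL) {
  stopifnot(inherits(pair, "ratiometric_pair"))
  total <- pair$I420 + pair$I473
  thr <- intensity_threshold
  if (is.null(mask)) {
    if (is.null(thr)) thr <- otsu_threshold(total)
    mask <- total > thr
  } else {
    stopifnot(all(dim(mask) == dim(total)))
    mask <- (mask != 0) & total > 0
    thr <- thr %||% 0
  }
  if (!any(mask))
    stop_cellmech(sprintf(
      "all pixels masked out (threshold %.3g, max total intensity %.3g)",
      thr, max(total)), "cellmech_empty_mask")
  gp <- matrix(NA_real_, nrow(total), ncol(total))
  gp[mask] <- (pair$I420[mask] - pair$I473[mask]) / total[mask]
  structure(list(gp = gp, mask = mask, intensity_threshold = thr),
            class = "gp_map")
}

#' GP frequency distribution
#'
#' Normalized histogram of masked-in GP values over [-1, 1].
#'
#' @param map a \code{\link{compute_gp_map}} result.
#' @param n_bins number of equal-width bins spanning [-1, 1] (>= 2).
#' @return Object of class \code{gp_distribution}: \code{bin_centers},
#'   \code{frequencies} (summing to 1), \code{n_pixels}, and a
#'   \code{gaussian_fit} slot filled by \code{\link{fit_gaussian}}.
#' @export
gp_frequency_distribution <- function(map, n_bins = 100L) {
  stopifnot(inherits(map, "gp_map"))
  if (n_bins < 2L)
    stop_cellmech("n_bins must be >= 2", "cellmech_spec_error")
  vals <- map$gp[map$mask]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop_cellmech("GP map has no valid pixels", "cellmech_empty_mask")
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  # left-closed bins, except the last which includes +1
  bin <- pmin(findInterval(vals, breaks, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, n_bins)
  structure(list(bin_centers = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2,
                 frequencies = counts / length(vals),
                 n_pixels = length(vals), gaussian_fit = NULL),
            class = "gp_distribution")
}

#' Fit a single Gaussian to a GP frequency distribution
#'
#' Nonlinear least-squares fit of \code{A exp(-(x - mu)^2 / (2 sd^2))} to
#' the bin frequencies, initialized from the histogram moments.
#' Non-convergence (including degenerate histograms with fewer than 5
#' nonzero bins) is flagged, never silently zeroed.
#'
#' @param dist a \code{\link{gp_frequency_distribution}} result.
#' @return The distribution with \code{gaussian_fit}: list(amplitude, mean,
#'   sd, residual (root-mean-square), converged).
#' @export
fit_gaussian <- function(dist) {
  stopifnot(inherits(dist, "gp_distribution"))
  x <- dist$bin_centers; f <- dist$frequencies
  fail <- function(note) {
    dist$gaussian_fit <- list(amplitude = NA_real_, mean = NA_real_,
                              sd = NA_real_, residual = NA_real_,
                              converged = FALSE, note = note)
    dist
  }
  if (sum(f > 0) < 5L) return(fail("fewer than 5 nonzero bins"))
  mu0 <- sum(x * f)
  sd0 <- sqrt(max(sum((x - mu0)^2 * f), 1e-8))
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(A = max(f), mu = mu0, s = sd0),
                      lower = c(0, -1, 1e-6), upper = c(Inf, 1, 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit failed"))
  cf <- stats::coef(fit)
  dist$gaussian_fit <- list(amplitude = unname(cf["A"]),
                            mean = unname(cf["mu"]), sd = unname(cf["s"]),
                            residual = sqrt(mean(stats::resid(fit)^2)),
                            converged = TRUE, note = NULL)
  dist
}

#' Condition-difference curve between two GP distributions
#'
#' Per-bin difference of two normalized GP frequency distributions (e.g.
#' control minus treated); since both inputs sum to one, the difference
#' curve sums to zero.
#'
#' @param dist_a,dist_b distributions with identical binning.
#' @param minuend which argument is the minuend: \code{"a"} (default,
#'   curve = a - b) or \code{"b"}.
#' @return Object of class \code{gp_difference_curve} with
#'   \code{bin_centers}, \code{delta_frequency} and \code{minuend}.
#' @export
gp_difference_curve <- function(dist_a, dist_b, minuend = c("a", "b")) {
  stopifnot(inherits(dist_a, "gp_distribution"),
            inherits(dist_b, "gp_distribution"))
  minuend <- match.arg(minuend)
  if (length(dist_a$bin_centers) != length(dist_b$bin_centers) ||
      any(abs(dist_a$bin_centers - dist_b$bin_centers) > 1e-12))
    stop_cellmech("distributions have different binning",
                  "cellmech_shape_error")
  delta <- if (minuend == "a") dist_a$frequencies - dist_b$frequencies
           else dist_b$frequencies - dist_a$frequencies
  structure(list(bin_centers = dist_a$bin_centers, delta_frequency = delta,
                 minuend = minuend), class = "gp_difference_curve")
}

#' Mean GP over the masked-in pixels
#'
#' @param map a \code{\link{compute_gp_map}} result.
#' @return Scalar mean GP.
#' @export
total_mean_gp <- function(map) {
  stopifnot(inherits(map, "gp_map"))
  vals <- map$gp[map$mask]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop_cellmech("GP map has no valid pixels", "cellmech_empty_mask")
  mean(vals)
}

#' Overlap of high-GP regions with the nanoparticle channel
#'
#' Fraction of high-GP pixels (GP above \code{gp_threshold}, within the GP
#' mask) that also exceed the nanoparticle-channel threshold. One
#' operationalization of "nanoparticle signal colocalizes with high-GP
#' (ordered) membrane domains".
#'
#' @param map a \code{gp_map}.
#' @param np_channel registered nanoparticle-channel matrix.
#' @param gp_threshold GP cutoff defining high-GP pixels.
#' @param np_threshold intensity cutoff defining nanoparticle presence.
#' @return Overlap fraction in [0, 1]; \code{NaN} with attribute
#'   \code{undefined = TRUE} (plus a warning) when no high-GP pixels exist.
#' @export
high_gp_colocalization <- function(map, np_channel, gp_threshold,
                                   np_threshold) {
  stopifnot(inherits(map, "gp_map"))
  stopifnot(all(dim(np_channel) == dim(map$gp)))
  high <- map$mask & !is.na(map$gp) & map$gp > gp_threshold
  if (!any(high)) {
    warning("no pixels above gp_threshold; overlap fraction undefined")
    return(structure(NaN, undefined = TRUE))
  }
  sum(np_channel[high] > np_threshold) / sum(high)
}
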