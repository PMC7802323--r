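# Single-cell migration metrics and group-comparison statistics.

#' Construct a cell track
#'
#' @param t_min timestamps in minutes (strictly increasing, uniform).
#' @param x_um,y_um positions in um.
#' @param cell_id identifier.
#' @return Object of class \code{cell_track} (a data frame).
#' @export
cell_track <- function(t_min, x_um, y_um, cell_id = 1L) {
  stopifnot(length(t_min) == length(x_um), length(x_um) == length(y_um))
  if (length(t_min) >= 2 && any(diff(t_min) <= 0))
    stop_cellmech("timestamps must be strictly increasing",
                  "cellmech_track_error")
  structure(data.frame(cell_id = cell_id, t_min = t_min,
                       x_um = x_um, y_um = y_um),
            class = c("cell_track", "data.frame"))
}

#' Bridge short gaps in a sampled track
#'
#' Missing samples (timestamps absent from the uniform grid) are filled by
#' linear interpolation when a gap spans at most \code{max_gap} missing
#' samples; longer gaps split the track into independent segments.
#'
#' @param track a \code{\link{cell_track}} or data frame with
#'   \code{t_min}, \code{x_um}, \code{y_um}.
#' @param interval_min sampling interval in minutes.
#' @param max_gap maximum number of consecutive missing samples to bridge.
#' @return List of \code{cell_track} segments with uniform timestamps.
#' @export
bridge_track_gaps <- function(track, interval_min, max_gap = 2L) {
  ord <- order(track$t_min)
  t <- track$t_min[ord]; x <- track$x_um[ord]; y <- track$y_um[ord]
  steps <- round(diff(t) / interval_min)
  cut_after <- which(steps > max_gap + 1)
  bounds <- c(0, cut_after, length(t))
  segs <- list()
  for (s in seq_len(length(bounds) - 1)) {
    ix <- (bounds[s] + 1):bounds[s + 1]
    if (length(ix) < 2) next
    tt <- seq(t[ix[1]], t[ix[length(ix)]], by = interval_min)
    segs[[length(segs) + 1]] <- cell_track(
      tt, stats::approx(t[ix], x[ix], xout = tt)$y,
      stats::approx(t[ix], y[ix], xout = tt)$y,
      cell_id = track$cell_id[1] %||% 1L)
  }
  segs
}

#' Migration metrics of a single track
#'
#' Travel distance is the sum of consecutive step lengths; mean velocity is
#' travel distance over elapsed time (path definition, matching travel
#' distance, not a per-step average); net displacement is the straight-line
#' start-to-end distance. Instantaneous per-step speeds are also returned.
#'
#' @param track a \code{\link{cell_track}} (>= 2 positions, uniformly
#'   sampled).
#' @return List: \code{path_distance_um}, \code{net_displacement_um},
#'   \code{mean_velocity_um_min}, \code{step_speeds_um_min},
#'   \code{duration_min}.
#' @export
track_metrics <- function(track) {
  t <- track$t_min; x <- track$x_um; y <- track$y_um
  if (length(t) < 2)
    stop_cellmech("track needs at least 2 positions", "cellmech_track_error")
  dt <- diff(t)
  if (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop_cellmech("track timestamps must be uniform and increasing",
                  "cellmech_track_error")
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  dist <- sum(steps)
  elapsed <- t[length(t)] - t[1]
  list(path_distance_um = dist,
       net_displacement_um = sqrt((x[length(x)] - x[1])^2 +
                                  (y[length(y)] - y[1])^2),
       mean_velocity_um_min = dist / elapsed,
       step_speeds_um_min = steps / dt,
       duration_min = elapsed)
}

#' One-way ANOVA with Bonferroni pairwise comparisons
#'
#' Group means +/- SD, the one-way ANOVA F-test, and all pairwise t-tests
#' (pooled SD) with Bonferroni adjustment (adjusted p = min(1, m * raw)
#' over the m pairs); the significance flag uses p < 0.05.
#'
#' @param values numeric vector of observations.
#' @param groups factor (or coercible) of the same length.
#' @param alpha significance level (default 0.05).
#' @return List: \code{groups} (data frame of n, mean, sd),
#'   \code{anova_F}, \code{anova_p}, \code{pairs} (data frame of pairwise
#'   raw and Bonferroni-adjusted p with significance flags).
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop_cellmech("need at least 2 groups", "cellmech_stats_error")
  if (any(table(groups) < 2))
    stop_cellmech("need at least 2 values per group", "cellmech_stats_error")
  sds <- tapply(values, groups, stats::sd)
  if (all(sds == 0))
    stop_cellmech("zero within-group variance in every group",
                  "cellmech_stats_error")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  raw <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  pairs <- do.call(rbind, lapply(rownames(raw), function(r)
    do.call(rbind, lapply(colnames(raw), function(c)
      if (!is.na(raw[r, c])) data.frame(group1 = c, group2 = r,
                                        p_raw = raw[r, c]) else NULL))))
  pairs$p_adjusted <- pmin(1, pairs$p_raw * nrow(pairs))
  pairs$significant <- pairs$p_adjusted < alpha
  list(groups = data.frame(group = levels(groups),
                           n = as.vector(table(groups)),
                           mean = as.vector(tapply(values, groups, mean)),
                           sd = as.vector(sds)),
       anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       pairs = pairs)
}
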