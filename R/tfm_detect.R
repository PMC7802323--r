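# Subpixel pillar localization and lattice reconstruction.

#' Detect pillar positions in a single frame
#'
#' Blob detection (local maxima of a lightly smoothed frame above an
#' adaptive threshold) followed by intensity-weighted centroid refinement
#' in a window of radius pitch/2 around each blob, with one re-centering
#' iteration. Weights are background-subtracted and floored at the noise
#' level so the refinement is unbiased for symmetric spots.
#'
#' @param frame numeric image matrix (bright pillars on dark background).
#' @param geom a \code{\link{pillar_geometry}} (supplies the pitch).
#' @param pixel_size um/pixel.
#' @return Data frame with subpixel positions \code{x_um}, \code{y_um} and
#'   the blob \code{peak} intensity; at least 4 detections or an error.
#' @export
detect_pillars <- function(frame, geom, pixel_size) {
  stopifnot(is.matrix(frame), inherits(geom, "pillar_geometry"))
  pitch_px <- geom$pitch_um / pixel_size
  if (pitch_px <= 3)
    stop_cellmech("pitch must exceed 3 pixels for a resolvable array",
                  "cellmech_detect_error")
  ny <- nrow(frame); nx <- ncol(frame)
  sm <- gaussian_smooth(frame, 1)
  bg <- stats::median(frame)
  noise <- stats::mad(frame)
  thr <- bg + max(6 * noise, 0.25 * (max(sm) - bg))
  if (max(sm) <= bg || !any(sm > thr))
    stop_cellmech("no pillar-like blobs above background",
                  "cellmech_detect_error")

  # local maxima of the smoothed image (>= all 8 neighbours, above thr)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- sm
  is_max <- sm > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & sm >= pad[2:(ny + 1) + di, 2:(nx + 1) + dj]
  }
  peaks <- which(is_max, arr.ind = TRUE)
  if (nrow(peaks) == 0)
    stop_cellmech("no pillar-like blobs above background",
                  "cellmech_detect_error")

  # merge duplicate maxima (plateaus / noise) closer than pitch/2
  ord <- order(sm[peaks], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  min_d2 <- (pitch_px / 2)^2
  for (a in seq_len(nrow(peaks))) {
    if (!keep[a]) next
    if (a < nrow(peaks)) {
      b <- (a + 1):nrow(peaks)
      d2 <- (peaks[b, 1] - peaks[a, 1])^2 + (peaks[b, 2] - peaks[a, 2])^2
      keep[b[d2 < min_d2]] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]

  r <- max(3L, as.integer(floor(pitch_px / 2)) - 1L)
  floor_level <- bg + 3 * noise
  centroid <- function(i0, j0) {
    ii <- max(1L, i0 - r):min(ny, i0 + r)
    jj <- max(1L, j0 - r):min(nx, j0 + r)
    w <- frame[ii, jj, drop = FALSE] - floor_level
    w[w < 0] <- 0
    s <- sum(w)
    if (s <= 0) return(c(NA_real_, NA_real_))
    c(sum(t(w) * (jj - 1)) / s, sum(w * (ii - 1)) / s) # (x, y), 0-based px
  }
  pos <- t(apply(peaks, 1, function(p) {
    c0 <- centroid(p[1], p[2])
    if (anyNA(c0)) return(c0)
    centroid(as.integer(round(c0[2])) + 1L, as.integer(round(c0[1])) + 1L)
  }))
  ok <- !is.na(pos[, 1])
  if (sum(ok) < 4)
    stop_cellmech("fewer than 4 pillars detected; grid unrecoverable",
                  "cellmech_detect_error")
  data.frame(x_um = pos[ok, 1] * pixel_size, y_um = pos[ok, 2] * pixel_size,
             peak = sm[peaks][ok])
}

#' Reconstruct the rest lattice of a pillar array
#'
#' Estimates the lattice orientation from nearest-neighbour direction
#' statistics, assigns integer lattice indices, and fits origin and basis
#' vectors by least squares, iteratively trimming detections that sit far
#' off their node (deflected pillars) so the rest grid is defined by the
#' undeflected majority. Rest position of every detection is its fitted
#' lattice node.
#'
#' @param positions data frame with \code{x_um}, \code{y_um} (>= 4 rows),
#'   e.g. from \code{\link{detect_pillars}} on a reference frame.
#' @param geom a \code{\link{pillar_geometry}} (pitch and lattice type).
#' @return Object of class \code{pillar_grid}: \code{origin} (um),
#'   \code{basis} (2x2 matrix, columns = basis vectors, um), \code{nodes}
#'   (pillar_id, i, j, rest_x_um, rest_y_um), \code{rms_residual_um} over
#'   the undeflected inliers, and the lattice type.
#' @export
reconstruct_grid <- function(positions, geom) {
  stopifnot(inherits(geom, "pillar_geometry"))
  P <- cbind(positions$x_um, positions$y_um)
  n <- nrow(P)
  if (is.null(n) || n < 4)
    stop_cellmech("need at least 4 positions to fit a lattice",
                  "cellmech_grid_error")
  pitch <- geom$pitch_um
  fold <- if (geom$lattice_type == "square") 4 else 6

  # orientation: circular mean of nearest-neighbour angles modulo the
  # lattice symmetry (90 deg square, 60 deg hexagonal)
  d2 <- as.matrix(stats::dist(P))^2
  diag(d2) <- Inf
  nn <- apply(d2, 1, which.min)
  v <- P[nn, , drop = FALSE] - P
  ang <- atan2(v[, 2], v[, 1])
  theta <- atan2(mean(sin(fold * ang)), mean(cos(fold * ang))) / fold

  basis_from <- function(theta) {
    a <- pitch * c(cos(theta), sin(theta))
    phi <- if (geom$lattice_type == "square") pi / 2 else pi / 3
    b <- pitch * c(cos(theta + phi), sin(theta + phi))
    cbind(a, b)
  }
  B <- basis_from(theta)
  origin <- colMeans(P)
  # integer lattice indices: remove the global fractional phase (estimated
  # circularly so a phase near 0.5 cannot split the rounding) before
  # rounding the lattice coordinates
  lattice_indices <- function(B, origin) {
    U <- solve(B, t(P) - origin)
    phase <- vapply(1:2, function(r)
      atan2(mean(sin(2 * pi * U[r, ])), mean(cos(2 * pi * U[r, ]))) /
        (2 * pi), numeric(1))
    t(round(U - phase))
  }
  keep <- rep(TRUE, n)
  for (iter in 1:3) {
    idx <- lattice_indices(B, origin)
    X <- cbind(1, idx)
    fit_x <- stats::lm.fit(X[keep, , drop = FALSE], P[keep, 1])
    fit_y <- stats::lm.fit(X[keep, , drop = FALSE], P[keep, 2])
    cf <- cbind(fit_x$coefficients, fit_y$coefficients)
    if (anyNA(cf)) break # degenerate (e.g. collinear detections)
    origin <- cf[1, ]
    B <- t(cf[2:3, , drop = FALSE])
    fitted <- t(origin + B %*% t(idx))
    res <- sqrt(rowSums((P - fitted)^2))
    thr <- max(4 * stats::mad(res[keep], center = 0), 0.03 * pitch)
    keep <- res <= thr
    if (sum(keep) < 4)
      stop_cellmech("lattice fit degenerate: too few undeflected pillars",
                    "cellmech_grid_error")
  }
  idx <- lattice_indices(B, origin)
  fitted <- t(origin + B %*% t(idx))
  res <- sqrt(rowSums((P - fitted)^2))
  rms <- sqrt(mean(res[keep]^2))
  if (rms > pitch / 4)
    stop_cellmech(sprintf(
      "lattice fit residual %.3g um exceeds pitch/4; wrong lattice type or pitch?",
      rms), "cellmech_grid_error")
  if (anyDuplicated(idx)) {
    # unique assignment: keep the detection closest to each node
    ord <- order(res)
    dup <- duplicated(idx[ord, , drop = FALSE])
    keep_rows <- ord[!dup]
  } else keep_rows <- seq_len(n)
  nodes <- data.frame(i = idx[keep_rows, 1], j = idx[keep_rows, 2],
                      rest_x_um = fitted[keep_rows, 1],
                      rest_y_um = fitted[keep_rows, 2])
  nodes <- nodes[order(nodes$j, nodes$i), ]
  nodes <- cbind(pillar_id = seq_len(nrow(nodes)), nodes)
  rownames(nodes) <- NULL
  structure(list(origin = origin, basis = B, nodes = nodes,
                 lattice_type = geom$lattice_type, pitch_um = pitch,
                 rms_residual_um = rms), class = "pillar_grid")
}

#' Track pillar deflections through a time-lapse stack
#'
#' Detects pillars in every frame and assigns each lattice node its nearest
#' detection, gated at pitch/2. The gate is applied around the node rest
#' position shifted by the previous frame's median displacement, so slow
#' cumulative stage drift cannot walk detections across node boundaries;
#' the raw displacement recorded is always detection minus rest position.
#' Nodes without a detection inside the gate are flagged as untracked, not
#' interpolated.
#'
#' @param stack numeric array \code{ny x nx x n_frames}.
#' @param grid a \code{\link{reconstruct_grid}} result valid for frame 1.
#' @param geom a \code{\link{pillar_geometry}}.
#' @param pixel_size um/pixel.
#' @return Object of class \code{deflection_field}: data frame with
#'   pillar_id, frame, rest positions, raw displacements \code{dx_um},
#'   \code{dy_um} and \code{tracked}; the grid is attached as an attribute.
#' @export
track_pillars <- function(stack, grid, geom, pixel_size) {
  stopifnot(length(dim(stack)) == 3, inherits(grid, "pillar_grid"))
  nodes <- grid$nodes
  gate2 <- (geom$pitch_um / 2)^2
  offset <- c(0, 0)
  frames <- vector("list", dim(stack)[3])
  for (t in seq_len(dim(stack)[3])) {
    det <- detect_pillars(stack[, , t], geom, pixel_size)
    D <- cbind(det$x_um, det$y_um)
    dx <- dy <- rep(NA_real_, nrow(nodes))
    used <- rep(FALSE, nrow(D))
    pred <- cbind(nodes$rest_x_um + offset[1], nodes$rest_y_um + offset[2])
    # nearest detection per node, gated; greedy by distance for uniqueness
    cand <- do.call(rbind, lapply(seq_len(nrow(nodes)), function(k) {
      d2 <- (D[, 1] - pred[k, 1])^2 + (D[, 2] - pred[k, 2])^2
      m <- which.min(d2)
      if (d2[m] < gate2) c(k, m, d2[m]) else NULL
    }))
    if (!is.null(cand)) {
      cand <- cand[order(cand[, 3]), , drop = FALSE]
      taken_node <- rep(FALSE, nrow(nodes))
      for (r in seq_len(nrow(cand))) {
        k <- cand[r, 1]; m <- cand[r, 2]
        if (taken_node[k] || used[m]) next
        taken_node[k] <- TRUE; used[m] <- TRUE
        dx[k] <- D[m, 1] - nodes$rest_x_um[k]
        dy[k] <- D[m, 2] - nodes$rest_y_um[k]
      }
    }
    if (mean(used) < 0.8)
      stop_cellmech(sprintf(
        "frame %d: %.0f%% of detections unassigned to lattice nodes",
        t, 100 * (1 - mean(used))), "cellmech_track_error")
    tracked <- !is.na(dx)
    if (any(tracked)) offset <- c(stats::median(dx[tracked]),
                                  stats::median(dy[tracked]))
    frames[[t]] <- data.frame(pillar_id = nodes$pillar_id, frame = t,
                              rest_x_um = nodes$rest_x_um,
                              rest_y_um = nodes$rest_y_um,
                              dx_um = dx, dy_um = dy, tracked = tracked)
  }
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  structure(out, class = c("deflection_field", "data.frame"),
            grid = grid, corrected = FALSE)
}
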