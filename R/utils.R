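# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Otsu's between-class variance threshold on a numeric image.
# Returns a scalar threshold on the intensity scale of `x`.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids) / pmax(w1, 1)
  m2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# Separable Gaussian smoothing with reflected edges; sigma in pixels.
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    # reflect-pad rows then convolve columns of the padded matrix
    n <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    idx <- pmin(pmax(idx, 1L), n)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[(i - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# 4-connected component labelling for small binary masks.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  ny <- nrow(mask); nx <- ncol(mask)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% ny + 1L
      j <- (p - 1L) %/% ny + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1L && ii <= ny && jj >= 1L && jj <= nx) {
          q <- (jj - 1L) * ny + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Pixel-center coordinates (um) of all TRUE pixels of a mask.
mask_coords_um <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = (idx[, 2] - 1) * pixel_size, y = (idx[, 1] - 1) * pixel_size)
}

# Boundary pixels of a mask (TRUE pixels with at least one 4-neighbour FALSE
# or on the image edge).
mask_boundary <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- mask
  core <- pad[2:(ny + 1), 2:(nx + 1)]
  nb <- pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
    pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  core & !nb
}

stop_cellmech <- function(msg, class) {
  stop(structure(class = c(class, "cellmech_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
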