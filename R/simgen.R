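# Synthetic-data generators: pillar-array movies, two-channel laurdan scenes,
# cell migration tracks and omics tables, all with planted ground truth.

#' Pillar-array scene specification
#'
#' Describes a synthetic micropillar time-lapse: lattice geometry, optics,
#' noise, global stage drift and planted per-pillar deflections.
#'
#' @param image_shape integer vector \code{c(ny, nx)} in pixels.
#' @param pixel_size pixel size in um/pixel.
#' @param n_frames number of frames.
#' @param lattice_pitch centre-to-centre pillar distance in um.
#' @param pillar_diameter pillar diameter in um (must be < pitch).
#' @param lattice_type \code{"square"} or \code{"hexagonal"}.
#' @param psf_sigma point-spread-function sigma in pixels (isotropic
#'   Gaussian); the rendered spot variance is \code{psf_sigma^2 + R^2/4}
#'   with \code{R} the pillar radius, the second moment of a blurred disk.
#' @param photon_level peak signal amplitude in counts.
#' @param background constant background level in counts.
#' @param drift_per_frame global stage drift per frame, \code{c(dx, dy)} um;
#'   cumulative drift at frame t is \code{(t-1) * drift_per_frame}.
#' @param deflections \code{NULL} or a data frame with columns
#'   \code{pillar_id}, \code{dx_um}, \code{dy_um} and optionally
#'   \code{frame}; without a \code{frame} column the deflection is constant
#'   over the movie. Magnitudes must stay below \code{pitch/2} so the
#'   tracker can identify nodes.
#' @param cell_mask \code{NULL} or a logical matrix of shape
#'   \code{image_shape} marking the cell footprint. Deflections may only be
#'   planted on pillars under the mask.
#' @param noise list with \code{poisson} (logical, shot noise) and
#'   \code{read_sd} (Gaussian read noise sd in counts).
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return An object of class \code{pillar_scene_spec}.
#' @export
pillar_scene_spec <- function(image_shape = c(256L, 256L), pixel_size = 0.1,
                              n_frames = 1L, lattice_pitch = 1.8,
                              pillar_diameter = 0.9,
                              lattice_type = c("square", "hexagonal"),
                              psf_sigma = 1.5, photon_level = 500,
                              background = 10, drift_per_frame = c(0, 0),
                              deflections = NULL, cell_mask = NULL,
                              noise = list(poisson = TRUE, read_sd = 0),
                              seed = 1L) {
  lattice_type <- match.arg(lattice_type)
  if (!(lattice_pitch > pillar_diameter && pillar_diameter > 0))
    stop_cellmech("need pitch > diameter > 0", "cellmech_spec_error")
  if (n_frames < 1L)
    stop_cellmech("n_frames must be >= 1", "cellmech_spec_error")
  if (!is.null(cell_mask)) {
    cell_mask <- cell_mask != 0
    if (!all(dim(cell_mask) == image_shape))
      stop_cellmech("cell_mask shape must equal image_shape",
                    "cellmech_spec_error")
  }
  spec <- structure(list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_frames = as.integer(n_frames), lattice_pitch = lattice_pitch,
    pillar_diameter = pillar_diameter, lattice_type = lattice_type,
    psf_sigma = psf_sigma, photon_level = photon_level,
    background = background, drift_per_frame = drift_per_frame,
    deflections = deflections, cell_mask = cell_mask,
    noise = utils::modifyList(list(poisson = TRUE, read_sd = 0), noise),
    seed = as.integer(seed)), class = "pillar_scene_spec")
  validate_deflections(spec)
  spec
}

# Rest lattice covering the field of view with a one-pitch margin.
#' Rest lattice positions of a pillar scene
#'
#' @param spec a \code{\link{pillar_scene_spec}}.
#' @return Data frame with \code{pillar_id}, lattice indices \code{i},
#'   \code{j}, rest positions \code{x_um}, \code{y_um} and the
#'   \code{under_cell} flag.
#' @export
pillar_lattice_positions <- function(spec) {
  p <- spec$lattice_pitch
  lim_x <- (spec$image_shape[2] - 1) * spec$pixel_size - p
  lim_y <- (spec$image_shape[1] - 1) * spec$pixel_size - p
  if (spec$lattice_type == "square") {
    is <- seq(0, floor((lim_x - p) / p))
    js <- seq(0, floor((lim_y - p) / p))
    grid <- expand.grid(i = is, j = js)
    x <- p + grid$i * p
    y <- p + grid$j * p
  } else {
    row_h <- p * sqrt(3) / 2
    js <- seq(0, floor((lim_y - p) / row_h))
    grid <- do.call(rbind, lapply(js, function(j) {
      off <- if (j %% 2 == 1) p / 2 else 0
      is <- seq(0, floor((lim_x - p - off) / p))
      data.frame(i = is, j = j, x = p + off + is * p)
    }))
    x <- grid$x
    y <- p + grid$j * row_h
    grid <- grid[c("i", "j")]
  }
  under <- rep(FALSE, length(x))
  if (!is.null(spec$cell_mask)) {
    col <- pmin(pmax(round(x / spec$pixel_size) + 1, 1), spec$image_shape[2])
    row <- pmin(pmax(round(y / spec$pixel_size) + 1, 1), spec$image_shape[1])
    under <- spec$cell_mask[cbind(row, col)]
  }
  data.frame(pillar_id = seq_along(x), i = grid$i, j = grid$j,
             x_um = x, y_um = y, under_cell = under)
}

validate_deflections <- function(spec) {
  d <- spec$deflections
  if (is.null(d)) return(invisible(TRUE))
  stopifnot(all(c("pillar_id", "dx_um", "dy_um") %in% names(d)))
  mag <- sqrt(d$dx_um^2 + d$dy_um^2)
  if (any(mag >= spec$lattice_pitch / 2))
    stop_cellmech("deflection magnitude must be < pitch/2 (tracker identifiability)",
                  "cellmech_spec_error")
  lat <- pillar_lattice_positions(spec)
  if (!all(d$pillar_id %in% lat$pillar_id))
    stop_cellmech("deflections reference unknown pillar ids",
                  "cellmech_spec_error")
  if (!is.null(spec$cell_mask)) {
    under <- lat$under_cell[match(d$pillar_id, lat$pillar_id)]
    if (!all(under))
      stop_cellmech("deflections may only be planted on pillars inside cell_mask",
                    "cellmech_spec_error")
  }
  invisible(TRUE)
}

#' Plant random deflections on under-cell pillars
#'
#' Convenience generator for scene construction: draws random directions and
#' magnitudes for a subset of the pillars under the cell mask.
#'
#' @param lattice output of \code{\link{pillar_lattice_positions}}.
#' @param n number of pillars to deflect (capped at available pillars).
#' @param magnitude_range min/max deflection magnitude in um.
#' @param under_cell_only restrict to pillars with \code{under_cell} TRUE.
#' @param seed RNG seed.
#' @return Deflection data frame suitable for \code{pillar_scene_spec}.
#' @export
plant_random_deflections <- function(lattice, n, magnitude_range = c(0.1, 0.4),
                                     under_cell_only = TRUE, seed = 1L) {
  pool <- if (under_cell_only) lattice$pillar_id[lattice$under_cell]
          else lattice$pillar_id
  with_seed(seed, {
    ids <- sample(pool, min(n, length(pool)))
    mag <- stats::runif(length(ids), magnitude_range[1], magnitude_range[2])
    ang <- stats::runif(length(ids), 0, 2 * pi)
    data.frame(pillar_id = ids, dx_um = mag * cos(ang), dy_um = mag * sin(ang))
  })
}

#' Simulate a micropillar time-lapse with known ground truth
#'
#' Renders each pillar as a PSF-blurred bright disk on a dark background at
#' its rest position plus planted deflection plus cumulative stage drift,
#' with optional Poisson shot noise and Gaussian read noise.
#'
#' @param spec a \code{\link{pillar_scene_spec}}.
#' @return List with \code{stack} (numeric array \code{ny x nx x n_frames}),
#'   \code{truth} (per pillar, per frame: rest position, deflection, drift,
#'   reference/under-cell flags), \code{lattice} (rest lattice) and the
#'   input \code{spec}.
#' @export
simulate_pillar_sequence <- function(spec) {
  stopifnot(inherits(spec, "pillar_scene_spec"))
  validate_deflections(spec)
  lat <- pillar_lattice_positions(spec)
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  npil <- nrow(lat)
  d <- spec$deflections
  # under_cell truth: pillars under the mask, or (no mask) deflected pillars
  under <- lat$under_cell
  if (is.null(spec$cell_mask) && !is.null(d))
    under <- under | lat$pillar_id %in% d$pillar_id

  r_px <- (spec$pillar_diameter / 2) / spec$pixel_size
  sigma_eff <- sqrt(spec$psf_sigma^2 + r_px^2 / 4)
  win <- ceiling(4 * sigma_eff)

  defl_at <- function(frame) {
    dx <- dy <- numeric(npil)
    if (!is.null(d)) {
      dd <- if ("frame" %in% names(d)) d[d$frame == frame, , drop = FALSE] else d
      k <- match(dd$pillar_id, lat$pillar_id)
      dx[k] <- dd$dx_um; dy[k] <- dd$dy_um
    }
    cbind(dx, dy)
  }

  stack <- array(0, dim = c(ny, nx, spec$n_frames))
  truth <- vector("list", spec$n_frames)
  with_seed(spec$seed, {
    for (t in seq_len(spec$n_frames)) {
      drift <- (t - 1) * spec$drift_per_frame
      dxy <- defl_at(t)
      cx <- (lat$x_um + dxy[, 1] + drift[1]) / spec$pixel_size # 0-based px
      cy <- (lat$y_um + dxy[, 2] + drift[2]) / spec$pixel_size
      img <- matrix(spec$background, ny, nx)
      for (k in seq_len(npil)) {
        j0 <- round(cx[k]); i0 <- round(cy[k])
        jj <- max(0, j0 - win):min(nx - 1, j0 + win)
        ii <- max(0, i0 - win):min(ny - 1, i0 + win)
        if (!length(jj) || !length(ii)) next
        gx <- exp(-(jj - cx[k])^2 / (2 * sigma_eff^2))
        gy <- exp(-(ii - cy[k])^2 / (2 * sigma_eff^2))
        img[ii + 1, jj + 1] <- img[ii + 1, jj + 1] +
          spec$photon_level * outer(gy, gx)
      }
      if (isTRUE(spec$noise$poisson))
        img <- matrix(stats::rpois(length(img), img), ny, nx)
      if (spec$noise$read_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, spec$noise$read_sd),
                            ny, nx)
      stack[, , t] <- img
      truth[[t]] <- data.frame(
        pillar_id = lat$pillar_id, frame = t,
        rest_x_um = lat$x_um, rest_y_um = lat$y_um,
        defl_x_um = dxy[, 1], defl_y_um = dxy[, 2],
        drift_x_um = drift[1], drift_y_um = drift[2],
        is_reference = !under, under_cell = under)
    }
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(stack = stack, truth = truth,
       lattice = transform(lat, under_cell = under), spec = spec)
}

#' Laurdan scene specification
#'
#' @param gp_field numeric matrix of true per-pixel GP values in [-1, 1].
#' @param total_intensity_field scalar or matrix of total emission counts
#'   (the sum of the two channels before noise).
#' @param np_channel_field optional matrix: a correlated nanoparticle
#'   channel rendered as-is (plus noise).
#' @param noise list with \code{poisson} (logical) and \code{gaussian_sd}.
#' @param seed integer RNG seed.
#' @return Object of class \code{laurdan_scene_spec}.
#' @export
laurdan_scene_spec <- function(gp_field, total_intensity_field = 200,
                               np_channel_field = NULL,
                               noise = list(poisson = FALSE, gaussian_sd = 0),
                               seed = 1L) {
  stopifnot(is.matrix(gp_field))
  if (any(gp_field < -1 | gp_field > 1, na.rm = TRUE))
    stop_cellmech("gp_field must lie in [-1, 1]", "cellmech_spec_error")
  if (is.matrix(total_intensity_field))
    stopifnot(all(dim(total_intensity_field) == dim(gp_field)))
  structure(list(gp_field = gp_field,
                 total_intensity_field = total_intensity_field,
                 np_channel_field = np_channel_field,
                 noise = utils::modifyList(list(poisson = FALSE,
                                                gaussian_sd = 0), noise),
                 seed = as.integer(seed)),
            class = "laurdan_scene_spec")
}

#' Simulate a two-channel laurdan scene
#'
#' Channel intensities are constructed as \code{I420 = T (1 + GP) / 2} and
#' \code{I473 = T (1 - GP) / 2} before noise, so the GP formula inverts the
#' simulation analytically: at zero noise \code{\link{compute_gp_map}}
#' recovers the planted field wherever total intensity is positive (exactly,
#' when GP and T are exactly representable in binary floating point).
#'
#' @param spec a \code{\link{laurdan_scene_spec}}.
#' @return List with \code{I420}, \code{I473}, optional \code{np} channel,
#'   \code{gp_true} and the input \code{spec}.
#' @export
simulate_laurdan_cell <- function(spec) {
  stopifnot(inherits(spec, "laurdan_scene_spec"))
  gp <- spec$gp_field
  Tf <- spec$total_intensity_field
  if (!is.matrix(Tf)) Tf <- matrix(Tf, nrow(gp), ncol(gp))
  I420 <- Tf * (1 + gp) / 2
  I473 <- Tf * (1 - gp) / 2
  np <- spec$np_channel_field
  with_seed(spec$seed, {
    add_noise <- function(img) {
      if (is.null(img)) return(NULL)
      if (isTRUE(spec$noise$poisson))
        img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                      nrow(img), ncol(img))
      if (spec$noise$gaussian_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0,
                                         spec$noise$gaussian_sd),
                            nrow(img), ncol(img))
      img
    }
    I420 <- add_noise(I420); I473 <- add_noise(I473); np <- add_noise(np)
  })
  list(I420 = I420, I473 = I473, np = np, gp_true = gp, spec = spec)
}

#' Cell-track simulation specification
#'
#' @param n_cells number of cells.
#' @param sampling_interval sampling interval in minutes.
#' @param duration_h track duration in hours.
#' @param speed_model list with \code{mean} and \code{sd} (um/min) of the
#'   per-cell step speed; each cell moves at a constant speed drawn once.
#' @param turning list with \code{sd_rad}: sd of the per-step heading change
#'   (radians); 0 gives straight-line motion.
#' @param seed integer RNG seed.
#' @return Object of class \code{track_spec}.
#' @export
track_spec <- function(n_cells = 10L, sampling_interval = 5,
                       duration_h = 6,
                       speed_model = list(mean = 0.5, sd = 0.1),
                       turning = list(sd_rad = 0.4), seed = 1L) {
  if (sampling_interval <= 0)
    stop_cellmech("sampling_interval must be > 0", "cellmech_spec_error")
  structure(list(n_cells = as.integer(n_cells),
                 sampling_interval = sampling_interval,
                 duration_h = duration_h, speed_model = speed_model,
                 turning = turning, seed = as.integer(seed)),
            class = "track_spec")
}

#' Simulate single-cell migration tracks with known speeds
#'
#' Constant-speed persistent random walk: each cell draws one step speed
#' (truncated at a small positive floor) and performs heading increments
#' with the configured turning sd, sampled at the stated interval.
#'
#' @param spec a \code{\link{track_spec}}.
#' @return List with \code{tracks} (cell_id, t_min, x_um, y_um) and
#'   \code{truth} (cell_id, speed_um_min, path_length_um).
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  n_steps <- round(spec$duration_h * 60 / spec$sampling_interval)
  t_min <- seq(0, by = spec$sampling_interval, length.out = n_steps + 1)
  with_seed(spec$seed, {
    out <- lapply(seq_len(spec$n_cells), function(id) {
      speed <- max(stats::rnorm(1, spec$speed_model$mean,
                                spec$speed_model$sd), 1e-3)
      step <- speed * spec$sampling_interval
      heading <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(n_steps, 0, spec$turning$sd_rad))
      x <- c(0, cumsum(step * cos(heading)))
      y <- c(0, cumsum(step * sin(heading)))
      list(track = data.frame(cell_id = id, t_min = t_min, x_um = x, y_um = y),
           truth = data.frame(cell_id = id, speed_um_min = speed,
                              path_length_um = step * n_steps))
    })
    list(tracks = do.call(rbind, lapply(out, `[[`, "track")),
         truth = do.call(rbind, lapply(out, `[[`, "truth")))
  })
}

#' Simulate gene and metabolite tables with planted changes
#'
#' Baseline (control) levels are log-normal; treated levels are control
#' times the planted fold change times multiplicative log-normal noise.
#' Truth flags mark the features whose \emph{planted} change exceeds the
#' study cutoffs: fold change > \code{gene_cutoff} (in either direction)
#' for genes, relative change > \code{metab_cutoff} for metabolites.
#'
#' @param n_genes,n_metabolites table sizes.
#' @param gene_fc numeric vector of planted gene fold changes (ratio
#'   treated/control, > 0), assigned to the first \code{length(gene_fc)}
#'   genes; remaining genes get fold change 1.
#' @param metab_change numeric vector of planted relative metabolite changes
#'   (e.g. 0.25 = +25\%, -0.3 = -30\%); remaining metabolites unchanged.
#' @param noise_sd sd of multiplicative log-normal noise (0 = none).
#' @param gene_cutoff,metab_cutoff truth-flag cutoffs.
#' @param seed integer RNG seed.
#' @return List with \code{genes} and \code{metabolites} data frames
#'   (feature_id, class, control, treated, planted change, true_flag).
#' @export
simulate_omics_table <- function(n_genes = 100L, n_metabolites = 20L,
                                 gene_fc = numeric(0),
                                 metab_change = numeric(0),
                                 noise_sd = 0, gene_cutoff = 3,
                                 metab_cutoff = 0.2, seed = 1L) {
  stopifnot(all(gene_fc > 0), all(metab_change > -1))
  with_seed(seed, {
    make <- function(n, planted, prefix) {
      control <- stats::rlnorm(n, meanlog = 5, sdlog = 0.5)
      mult <- rep(1, n)
      mult[seq_along(planted)] <- planted
      noise <- if (noise_sd > 0) stats::rlnorm(n, 0, noise_sd) else 1
      data.frame(feature_id = sprintf("%s%04d", prefix, seq_len(n)),
                 control = control, treated = control * mult * noise,
                 planted = mult)
    }
    genes <- make(n_genes, gene_fc, "gene")
    genes$class <- "gene"
    genes$true_flag <- pmax(genes$planted, 1 / genes$planted) > gene_cutoff
    metab <- make(n_metabolites, 1 + metab_change, "metab")
    metab$class <- "metabolite"
    metab$planted <- metab$planted - 1
    metab$true_flag <- abs(metab$planted) > metab_cutoff
    list(genes = genes, metabolites = metab)
  })
}
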