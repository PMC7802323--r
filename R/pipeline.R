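# Orchestration: validated run configuration, stage execution, manifest.

#' Disk-shaped cell mask
#'
#' @param shape image shape \code{c(ny, nx)} in pixels.
#' @param radius_um disk radius in um.
#' @param pixel_size um/pixel.
#' @param center_um disk centre \code{c(x, y)} in um; image centre by
#'   default.
#' @return Logical matrix.
#' @export
disk_mask <- function(shape, radius_um, pixel_size, center_um = NULL) {
  center_um <- center_um %||%
    c((shape[2] - 1) / 2, (shape[1] - 1) / 2) * pixel_size
  x <- (matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1])) *
    pixel_size
  y <- (matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), shape[1])) *
    pixel_size
  (x - center_um[1])^2 + (y - center_um[2])^2 <= radius_um^2
}

#' Build and validate a pipeline run configuration
#'
#' @param stages character vector from \code{"tfm"}, \code{"gp"},
#'   \code{"tracks"}, \code{"omics"}; executed in that canonical order.
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param pillars,gp,tracks,omics stage-parameter lists; see the manifest
#'   of a default run for the full key set. Defaults follow the study
#'   conditions (1.8 um pitch, 0.9 um diameter, 1 um height, E = 2 MPa
#'   pillars; 5-min track sampling over 6 h; 3-fold gene and 20\%
#'   metabolite cutoffs).
#' @return Validated object of class \code{run_config}.
#' @export
run_config <- function(stages, out_dir, seed = 1L, pillars = list(),
                       gp = list(), tracks = list(), omics = list()) {
  cfg <- structure(list(
    stages = stages, out_dir = out_dir, seed = as.integer(seed),
    pillars = utils::modifyList(list(
      geometry = list(pitch_um = 1.8, diameter_um = 0.9, height_um = 1,
                      youngs_modulus_pa = 2e6, lattice_type = "square",
                      stiffness_override = NULL),
      scene = list(image_shape = c(240L, 240L), pixel_size = 0.1,
                   n_frames = 5L, psf_sigma = 1.5, photon_level = 500,
                   background = 10, drift_per_frame = c(0.05, 0),
                   read_sd = 0),
      mask_radius_um = 7, n_deflected = 12,
      deflection_range_um = c(0.1, 0.4), margin_um = 2), pillars),
    gp = utils::modifyList(list(
      shape = c(128L, 128L), gp_inside = 0.5, gp_outside = -0.25,
      domain_radius_um = 4, pixel_size = 0.1, total_intensity = 256,
      n_bins = 100L, intensity_threshold = 0, gaussian_sd = 0), gp),
    tracks = utils::modifyList(list(
      n_cells = 10L, interval_min = 5, duration_h = 6, speed_mean = 0.5,
      speed_sd = 0.1, turning_sd = 0.4), tracks),
    omics = utils::modifyList(list(
      n_genes = 100L, n_metabolites = 20L, gene_fc = c(4, 5, 0.2),
      metab_change = c(0.25, -0.3), noise_sd = 0, gene_cutoff = 3,
      metab_cutoff = 0.2), omics)), class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Schema-style validation with stage-specific checks; raises a
#' \code{cellmech_config_error} before any stage executes.
#'
#' @param cfg a \code{run_config} (or plain list with the same layout).
#' @return \code{cfg}, invisibly, when valid.
#' @export
validate_run_config <- function(cfg) {
  bad <- function(msg) stop_cellmech(msg, "cellmech_config_error")
  known <- c("tfm", "gp", "tracks", "omics")
  if (!length(cfg$stages) || !all(cfg$stages %in% known))
    bad(sprintf("stages must be a subset of: %s",
                paste(known, collapse = ", ")))
  if (!is.character(cfg$out_dir) || !nzchar(cfg$out_dir))
    bad("out_dir is required")
  if (!is.finite(cfg$seed)) bad("seed must be a finite integer")
  if ("tfm" %in% cfg$stages) {
    g <- cfg$pillars$geometry
    for (f in c("pitch_um", "diameter_um", "height_um",
                "youngs_modulus_pa"))
      if (is.null(g[[f]]) || !is.finite(g[[f]]) || g[[f]] <= 0)
        bad(sprintf("tfm stage: pillars$geometry$%s must be positive", f))
    s <- cfg$pillars$scene
    if (is.null(s$pixel_size) || s$pixel_size <= 0)
      bad("tfm stage: pillars$scene$pixel_size must be positive")
    if (g$pitch_um / s$pixel_size <= 3)
      bad("tfm stage: pitch must exceed 3 pixels")
  }
  if ("gp" %in% cfg$stages) {
    if (cfg$gp$n_bins < 2) bad("gp stage: n_bins must be >= 2")
    if (any(abs(c(cfg$gp$gp_inside, cfg$gp$gp_outside)) > 1))
      bad("gp stage: GP values must lie in [-1, 1]")
  }
  if ("tracks" %in% cfg$stages && cfg$tracks$interval_min <= 0)
    bad("tracks stage: interval_min must be positive")
  if ("omics" %in% cfg$stages && any(cfg$omics$gene_fc <= 0))
    bad("omics stage: gene fold changes must be positive")
  invisible(cfg)
}

#' Execute a pipeline run
#'
#' Runs the requested stages in dependency order, each simulating its
#' inputs and analysing them with the package operations, writing stage
#' outputs (TIFF/CSV/JSON) under \code{out_dir} and a manifest echoing the
#' configuration, package version and every artifact produced. A fixed
#' (config, seed) pair reproduces identical outputs.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return The manifest list, invisibly; also written to
#'   \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  log <- list()
  emit <- function(name) artifacts <<- c(artifacts, name)

  if ("tfm" %in% cfg$stages) {
    res <- run_tfm_stage(cfg)
    write_image_stack(res$sim$stack, file.path(cfg$out_dir, "pillars.tif"),
                      cfg$pillars$scene$pixel_size)
    write_pillar_table(res$sim$truth,
                       file.path(cfg$out_dir, "pillar_truth.csv"))
    write_pillar_table(res$field,
                       file.path(cfg$out_dir, "pillar_deflections.csv"))
    jsonlite::write_json(res$forces$summary,
                         file.path(cfg$out_dir, "tfm_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("pillars.tif"); emit("pillars.tif.json")
    emit("pillar_truth.csv"); emit("pillar_deflections.csv")
    emit("tfm_summary.json")
    log$tfm <- list(n_pillars = nrow(res$grid$nodes),
                    n_reference = sum(res$classes$is_reference),
                    n_under_cell = sum(res$classes$under_cell),
                    stiffness_nN_um = attr(res$field_f, "stiffness_nN_um"),
                    stiffness_source = attr(res$field_f, "stiffness_source"))
  }
  if ("gp" %in% cfg$stages) {
    res <- run_gp_stage(cfg)
    utils::write.csv(data.frame(bin_center = res$dist$bin_centers,
                                frequency = res$dist$frequencies),
                     file.path(cfg$out_dir, "gp_distribution.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(total_mean_gp = res$mean_gp,
                              n_pixels = res$dist$n_pixels,
                              gaussian_fit = res$fit$gaussian_fit),
                         file.path(cfg$out_dir, "gp_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("gp_distribution.csv"); emit("gp_summary.json")
    log$gp <- list(n_pixels = res$dist$n_pixels)
  }
  if ("tracks" %in% cfg$stages) {
    res <- run_tracks_stage(cfg)
    utils::write.csv(res$sim$tracks, file.path(cfg$out_dir, "tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(res$metrics, file.path(cfg$out_dir,
                                            "track_metrics.csv"),
                     row.names = FALSE)
    emit("tracks.csv"); emit("track_metrics.csv")
    log$tracks <- list(n_cells = nrow(res$metrics))
  }
  if ("omics" %in% cfg$stages) {
    res <- run_omics_stage(cfg)
    export_network_nodes(res$genes, res$metab,
                         file.path(cfg$out_dir, "network_nodes.csv"))
    emit("network_nodes.csv")
    log$omics <- list(
      genes_flagged = sum(res$genes$passes_filter, na.rm = TRUE),
      metabolites_flagged = sum(res$metab$passes_filter, na.rm = TRUE))
  }
  manifest <- list(package = "cellmech",
                   version = as.character(utils::packageVersion("cellmech")),
                   seed = cfg$seed, config = unclass(cfg),
                   stages = cfg$stages, artifacts = artifacts, log = log)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# --- stage runners (simulate with derived seeds, then analyse) -----------

run_tfm_stage <- function(cfg) {
  s <- cfg$pillars$scene; g <- cfg$pillars$geometry
  geom <- pillar_geometry(g$diameter_um, g$height_um, g$youngs_modulus_pa,
                          g$pitch_um, g$lattice_type,
                          g$stiffness_override)
  mask <- disk_mask(s$image_shape, cfg$pillars$mask_radius_um,
                    s$pixel_size)
  base <- pillar_scene_spec(
    image_shape = s$image_shape, pixel_size = s$pixel_size,
    n_frames = s$n_frames, lattice_pitch = g$pitch_um,
    pillar_diameter = g$diameter_um, lattice_type = g$lattice_type,
    psf_sigma = s$psf_sigma, photon_level = s$photon_level,
    background = s$background, drift_per_frame = s$drift_per_frame,
    cell_mask = mask, noise = list(poisson = TRUE, read_sd = s$read_sd),
    seed = cfg$seed)
  defl <- plant_random_deflections(pillar_lattice_positions(base),
                                   cfg$pillars$n_deflected,
                                   cfg$pillars$deflection_range_um,
                                   seed = cfg$seed + 1L)
  spec <- base; spec$deflections <- defl
  validate_deflections(spec)
  sim <- simulate_pillar_sequence(spec)
  det <- detect_pillars(sim$stack[, , 1], geom, s$pixel_size)
  grid <- reconstruct_grid(det, geom)
  field <- track_pillars(sim$stack, grid, geom, s$pixel_size)
  classes <- classify_reference_pillars(grid, mask, s$pixel_size,
                                        cfg$pillars$margin_um)
  field <- correct_drift(set_pillar_classes(field, classes))
  field_f <- compute_forces(field, geom)
  forces <- aggregate_cell_forces(field_f)
  list(sim = sim, grid = grid, classes = classes, field = field,
       field_f = field_f, forces = forces)
}

run_gp_stage <- function(cfg) {
  g <- cfg$gp
  gp_field <- matrix(g$gp_outside, g$shape[1], g$shape[2])
  gp_field[disk_mask(g$shape, g$domain_radius_um, g$pixel_size)] <-
    g$gp_inside
  spec <- laurdan_scene_spec(gp_field, g$total_intensity,
                             noise = list(poisson = FALSE,
                                          gaussian_sd = g$gaussian_sd),
                             seed = cfg$seed + 2L)
  scene <- simulate_laurdan_cell(spec)
  pair <- ratiometric_pair(pmax(scene$I420, 0), pmax(scene$I473, 0),
                           pixel_size = g$pixel_size)
  map <- compute_gp_map(pair, intensity_threshold = g$intensity_threshold)
  dist <- gp_frequency_distribution(map, g$n_bins)
  fit <- fit_gaussian(dist)
  list(scene = scene, map = map, dist = dist, fit = fit,
       mean_gp = total_mean_gp(map))
}

run_tracks_stage <- function(cfg) {
  t <- cfg$tracks
  sim <- simulate_tracks(track_spec(
    n_cells = t$n_cells, sampling_interval = t$interval_min,
    duration_h = t$duration_h,
    speed_model = list(mean = t$speed_mean, sd = t$speed_sd),
    turning = list(sd_rad = t$turning_sd), seed = cfg$seed + 3L))
  metrics <- do.call(rbind, lapply(split(sim$tracks, sim$tracks$cell_id),
    function(tr) {
      m <- track_metrics(tr)
      data.frame(cell_id = tr$cell_id[1],
                 path_distance_um = m$path_distance_um,
                 net_displacement_um = m$net_displacement_um,
                 mean_velocity_um_min = m$mean_velocity_um_min)
    }))
  rownames(metrics) <- NULL
  list(sim = sim, metrics = metrics)
}

run_omics_stage <- function(cfg) {
  o <- cfg$omics
  sim <- simulate_omics_table(o$n_genes, o$n_metabolites, o$gene_fc,
                              o$metab_change, o$noise_sd, o$gene_cutoff,
                              o$metab_cutoff, seed = cfg$seed + 4L)
  list(sim = sim,
       genes = fold_change_filter(sim$genes, o$gene_cutoff),
       metab = metabolite_change_filter(sim$metabolites, o$metab_cutoff))
}
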