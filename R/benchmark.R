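# Ground-truth recovery benchmark: the package's own validation loop for
# the full traction-force chain.

#' End-to-end traction-force recovery benchmark
#'
#' Simulates a pillar-array movie with planted deflections, stage drift and
#' shot noise, runs the complete analysis chain (detect, reconstruct grid,
#' track, classify references, correct drift, compute forces), matches
#' analysis nodes to ground-truth pillars by rest position, and reports the
#' per-pillar relative error of the recovered mean force magnitudes along
#' with the residual drift-corrected displacement of the reference pillars.
#'
#' @param seed integer scene seed.
#' @param n_frames movie length.
#' @param image_shape scene shape in pixels.
#' @param pixel_size um/pixel.
#' @param drift_per_frame stage drift per frame, um.
#' @param n_deflected number of planted deflections.
#' @param deflection_range_um min/max planted deflection magnitude.
#' @param photon_level peak signal counts.
#' @param mask_radius_um radius of the disk cell mask.
#' @param geom a \code{\link{pillar_geometry}}.
#' @return List: \code{per_pillar} (data frame of true vs recovered force
#'   magnitude and relative error), \code{median_rel_error},
#'   \code{max_rel_error}, \code{mean_reference_displacement_um} and the
#'   stiffness used.
#' @export
tfm_recovery_benchmark <- function(seed = 1L, n_frames = 20L,
                                   image_shape = c(240L, 240L),
                                   pixel_size = 0.1,
                                   drift_per_frame = c(0.05, 0),
                                   n_deflected = 12L,
                                   deflection_range_um = c(0.1, 0.4),
                                   photon_level = 500,
                                   mask_radius_um = 7,
                                   geom = pillar_geometry()) {
  mask <- disk_mask(image_shape, mask_radius_um, pixel_size)
  spec <- pillar_scene_spec(
    image_shape = image_shape, pixel_size = pixel_size,
    n_frames = n_frames, lattice_pitch = geom$pitch_um,
    pillar_diameter = geom$diameter_um, lattice_type = geom$lattice_type,
    photon_level = photon_level, drift_per_frame = drift_per_frame,
    cell_mask = mask, noise = list(poisson = TRUE, read_sd = 0),
    seed = seed)
  lat <- pillar_lattice_positions(spec)
  defl <- plant_random_deflections(lat, n_deflected, deflection_range_um,
                                   seed = seed + 1000L)
  spec$deflections <- defl
  validate_deflections(spec)
  sim <- simulate_pillar_sequence(spec)
  grid <- reconstruct_grid(detect_pillars(sim$stack[, , 1], geom,
                                          pixel_size), geom)
  field <- track_pillars(sim$stack, grid, geom, pixel_size)
  classes <- classify_reference_pillars(grid, mask, pixel_size)
  field <- compute_forces(correct_drift(set_pillar_classes(field, classes)),
                          geom)
  k <- as.numeric(attr(field, "stiffness_nN_um"))
  truth_pos <- lat[match(defl$pillar_id, lat$pillar_id), ]
  per_pillar <- do.call(rbind, lapply(seq_len(nrow(defl)), function(r) {
    true_f <- k * sqrt(defl$dx_um[r]^2 + defl$dy_um[r]^2)
    d2 <- (grid$nodes$rest_x_um - truth_pos$x_um[r])^2 +
      (grid$nodes$rest_y_um - truth_pos$y_um[r])^2
    nid <- grid$nodes$pillar_id[which.min(d2)]
    rec <- field$f_mag_nN[field$pillar_id == nid & field$tracked]
    data.frame(pillar_id = nid, true_force_nN = true_f,
               recovered_force_nN = mean(rec),
               rel_error = abs(mean(rec) - true_f) / true_f)
  }))
  ref <- field[field$is_reference & field$tracked, , drop = FALSE]
  list(per_pillar = per_pillar,
       median_rel_error = stats::median(per_pillar$rel_error),
       max_rel_error = max(per_pillar$rel_error),
       mean_reference_displacement_um =
         mean(sqrt(ref$cx_um^2 + ref$cy_um^2)),
       stiffness_nN_um = k, field = field, grid = grid, truth = sim$truth)
}
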