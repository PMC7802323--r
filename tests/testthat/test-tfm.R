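test_that("beam-theory stiffness matches an independent unit-checked evaluation", {
  # independent oracle in SI units: k = 3 E I / L^3, I = pi D^4 / 64
  E <- 2e6; D <- 0.9e-6; L <- 1e-6
  k_SI <- 3 * E * (pi * D^4 / 64) / L^3          # N/m
  k_nN_um <- k_SI * 1e9 / 1e6                     # nN/um (1 N/m = 1e3 nN/um)
  k <- pillar_stiffness(pillar_geometry(0.9, 1, 2e6))
  expect_equal(as.numeric(k), k_nN_um, tolerance = 1e-12)
  expect_equal(as.numeric(k), 193.2, tolerance = 1e-3)
  expect_identical(attr(k, "source"), "formula")
})

test_that("stiffness obeys the cantilever scaling laws", {
  base <- as.numeric(pillar_stiffness(pillar_geometry(0.9, 1, 2e6)))
  expect_equal(as.numeric(pillar_stiffness(pillar_geometry(1.8, 1, 2e6))),
               16 * base)
  expect_equal(as.numeric(pillar_stiffness(pillar_geometry(0.9, 2, 2e6))),
               base / 8)
  expect_equal(as.numeric(pillar_stiffness(pillar_geometry(0.9, 1, 4e6))),
               2 * base)
  expect_error(pillar_geometry(-1, 1, 2e6), class = "cellmech_spec_error")
})

test_that("a stiffness override is honoured with a discrepancy note", {
  geom <- pillar_geometry(0.9, 1, 2e6, stiffness_override = 24.2)
  expect_message(k <- pillar_stiffness(geom), "differs from")
  expect_equal(as.numeric(k), 24.2)
  expect_identical(attr(k, "source"), "override")
  expect_match(attr(k, "note"), "193")
})

test_that("pillars localize to subpixel accuracy on simulated scenes", {
  geom <- pillar_geometry()
  # zero noise: < 0.05 px
  sim <- simulate_pillar_sequence(small_pillar_spec(seed = 3))
  det <- detect_pillars(sim$stack[, , 1], geom, 0.1)
  expect_equal(nrow(det), nrow(sim$lattice))
  err_px <- vapply(seq_len(nrow(det)), function(i)
    min(sqrt((sim$lattice$x_um - det$x_um[i])^2 +
             (sim$lattice$y_um - det$y_um[i])^2)) / 0.1, numeric(1))
  expect_lt(max(err_px), 0.05)
  # photon level 500 with shot noise: RMS < 0.25 px
  simn <- simulate_pillar_sequence(pillar_scene_spec(
    image_shape = c(200L, 200L), pixel_size = 0.1, photon_level = 500,
    noise = list(poisson = TRUE, read_sd = 0), seed = 4))
  detn <- detect_pillars(simn$stack[, , 1], geom, 0.1)
  errn <- vapply(seq_len(nrow(detn)), function(i)
    min(sqrt((simn$lattice$x_um - detn$x_um[i])^2 +
             (simn$lattice$y_um - detn$y_um[i])^2)) / 0.1, numeric(1))
  expect_lt(sqrt(mean(errn^2)), 0.25)
  # blank frame -> degenerate input error
  expect_error(detect_pillars(matrix(10, 100, 100), geom, 0.1),
               class = "cellmech_detect_error")
})

test_that("grid reconstruction recovers exact, rotated and partly deflected lattices", {
  geom <- pillar_geometry()
  # perfect square lattice -> exact axis-aligned basis
  g <- expand.grid(i = 0:7, j = 0:7)
  P <- data.frame(x_um = 2 + 1.8 * g$i, y_um = 2 + 1.8 * g$j)
  grid <- reconstruct_grid(P, geom)
  expect_equal(abs(grid$basis), 1.8 * diag(2) %*% matrix(c(1, 0, 0, 1), 2),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(grid$rms_residual_um, 0, tolerance = 1e-9)
  # rotation by 7 degrees is recovered within 0.1 degree
  th <- 7 * pi / 180
  P7 <- data.frame(x_um = 3 + 1.8 * (g$i * cos(th) - g$j * sin(th)),
                   y_um = 3 + 1.8 * (g$i * sin(th) + g$j * cos(th)))
  g7 <- reconstruct_grid(P7, geom)
  ang <- atan2(g7$basis[2, 1], g7$basis[1, 1]) * 180 / pi
  expect_lt(abs(ang - 7), 0.1)
  # 10% of pillars deflected < pitch/4: rest positions still near-exact
  withr::with_seed(8, {
    Pd <- P
    hit <- sample(nrow(Pd), 6)
    mag <- runif(6, 0.2, 0.44); dir <- runif(6, 0, 2 * pi)
    Pd$x_um[hit] <- Pd$x_um[hit] + mag * cos(dir)
    Pd$y_um[hit] <- Pd$y_um[hit] + mag * sin(dir)
  })
  gd <- reconstruct_grid(Pd, geom)
  for (r in seq_len(nrow(P))) {
    d <- min(sqrt((gd$nodes$rest_x_um - P$x_um[r])^2 +
                  (gd$nodes$rest_y_um - P$y_um[r])^2))
    expect_lt(d / 0.1, 0.1) # 0.1 px at 0.1 um/px
  }
  expect_error(reconstruct_grid(P[1:3, ], geom),
               class = "cellmech_grid_error")
})

test_that("hexagonal lattices are simulated and reconstructed consistently", {
  geom <- pillar_geometry(lattice_type = "hexagonal")
  sim <- simulate_pillar_sequence(small_pillar_spec(
    lattice_type = "hexagonal"))
  grid <- reconstruct_grid(detect_pillars(sim$stack[, , 1], geom, 0.1),
                           geom)
  expect_equal(nrow(grid$nodes), nrow(sim$lattice))
  expect_lt(grid$rms_residual_um, 1e-3)
  # nearest-neighbour rest distance equals the pitch
  nn <- vapply(seq_len(nrow(grid$nodes)), function(k) {
    d <- sqrt((grid$nodes$rest_x_um - grid$nodes$rest_x_um[k])^2 +
              (grid$nodes$rest_y_um - grid$nodes$rest_y_um[k])^2)
    min(d[d > 0])
  }, numeric(1))
  expect_equal(nn, rep(1.8, length(nn)), tolerance = 1e-6)
})

test_that("tracking recovers planted deflections, drift and static scenes", {
  geom <- pillar_geometry()
  # static noiseless scene: displacements are numerically zero
  sim0 <- simulate_pillar_sequence(small_pillar_spec(n_frames = 2L))
  grid <- reconstruct_grid(detect_pillars(sim0$stack[, , 1], geom, 0.1),
                           geom)
  f0 <- track_pillars(sim0$stack, grid, geom, 0.1)
  expect_true(all(f0$tracked))
  expect_lt(max(abs(c(f0$dx_um, f0$dy_um))), 1e-3)
  # planted single-pillar deflection of 0.351 um recovered within 0.01 um
  spec <- small_pillar_spec(
    deflections = data.frame(pillar_id = 45L, dx_um = 0.351, dy_um = 0))
  simd <- simulate_pillar_sequence(spec)
  gridd <- reconstruct_grid(detect_pillars(simd$stack[, , 1], geom, 0.1),
                            geom)
  fd <- track_pillars(simd$stack, gridd, geom, 0.1)
  mags <- sqrt(fd$dx_um^2 + fd$dy_um^2)
  expect_equal(max(mags), 0.351, tolerance = 0.01 / 0.351)
  expect_equal(sum(mags > 0.05), 1L)
  # pure drift: all raw displacements equal the cumulative drift
  simdr <- simulate_pillar_sequence(small_pillar_spec(
    n_frames = 3L, drift_per_frame = c(0.1, -0.05)))
  griddr <- reconstruct_grid(detect_pillars(simdr$stack[, , 1], geom, 0.1),
                             geom)
  fdr <- track_pillars(simdr$stack, griddr, geom, 0.1)
  for (t in 1:3) {
    sel <- fdr$frame == t & fdr$tracked
    expect_equal(mean(fdr$dx_um[sel]), 0.1 * (t - 1), tolerance = 1e-2)
    expect_equal(mean(fdr$dy_um[sel]), -0.05 * (t - 1), tolerance = 1e-2)
  }
})

test_that("reference classification follows the dilated-mask geometry", {
  geom <- pillar_geometry()
  sim <- simulate_pillar_sequence(small_pillar_spec())
  grid <- reconstruct_grid(detect_pillars(sim$stack[, , 1], geom, 0.1),
                           geom)
  # empty mask: every pillar is a reference
  cls <- classify_reference_pillars(grid, matrix(FALSE, 200, 200), 0.1, 2)
  expect_true(all(cls$is_reference))
  # full mask: no reference pillars -> error
  expect_error(classify_reference_pillars(grid, matrix(TRUE, 200, 200),
                                          0.1, 2),
               class = "cellmech_reference_error")
  # disk mask with 2 um margin matches the point-in-dilated-disk oracle
  mask <- disk_mask(c(200, 200), 5, 0.1)
  cls2 <- classify_reference_pillars(grid, mask, 0.1, 2)
  ctr <- c(199 / 2, 199 / 2) * 0.1
  r_node <- sqrt((grid$nodes$rest_x_um - ctr[1])^2 +
                 (grid$nodes$rest_y_um - ctr[2])^2)
  oracle_ref <- r_node > 5 + 2
  oracle_under <- r_node <= 5
  # allow half-pixel slack right at the two circles
  fuzzy <- abs(r_node - 7) < 0.1 | abs(r_node - 5) < 0.1
  expect_equal(cls2$is_reference[!fuzzy], oracle_ref[!fuzzy])
  expect_equal(cls2$under_cell[!fuzzy], oracle_under[!fuzzy])
})

test_that("drift correction removes any global translation exactly", {
  geom <- pillar_geometry()
  sim <- simulate_pillar_sequence(small_pillar_spec(
    n_frames = 3L, drift_per_frame = c(0.08, 0.03)))
  grid <- reconstruct_grid(detect_pillars(sim$stack[, , 1], geom, 0.1),
                           geom)
  field <- track_pillars(sim$stack, grid, geom, 0.1)
  cls <- classify_reference_pillars(grid, matrix(FALSE, 200, 200), 0.1)
  field <- correct_drift(set_pillar_classes(field, cls))
  # all pillars are references here; corrected displacements vanish and the
  # per-frame reference mean is exactly zero by construction
  for (t in 1:3) {
    sel <- field$frame == t & field$tracked & field$is_reference
    expect_equal(mean(field$cx_um[sel]), 0, tolerance = 1e-12)
    expect_equal(mean(field$cy_um[sel]), 0, tolerance = 1e-12)
  }
  expect_lt(max(abs(c(field$cx_um, field$cy_um))), 1e-3)
  # synthetic translation invariance on the numbers themselves
  shifted <- field
  shifted$dx_um <- shifted$dx_um + 3.3
  shifted$dy_um <- shifted$dy_um - 1.1
  reshift <- correct_drift(shifted)
  expect_equal(reshift$cx_um, field$cx_um, tolerance = 1e-12)
  expect_equal(reshift$cy_um, field$cy_um, tolerance = 1e-12)
})

test_that("forces scale linearly with displacement and stiffness", {
  geom24 <- pillar_geometry(stiffness_override = 24.2)
  sim <- simulate_pillar_sequence(small_pillar_spec(
    deflections = data.frame(pillar_id = c(40L, 41L),
                             dx_um = c(0.351, 0.216), dy_um = 0)))
  geom <- pillar_geometry()
  grid <- reconstruct_grid(detect_pillars(sim$stack[, , 1], geom, 0.1),
                           geom)
  field <- track_pillars(sim$stack, grid, geom, 0.1)
  cls <- classify_reference_pillars(grid, matrix(FALSE, 200, 200), 0.1)
  # exclude the two deflected nodes from the reference set
  truth1 <- sim$truth[sim$truth$frame == 1 & !sim$truth$is_reference, ]
  defl_nodes <- vapply(seq_len(nrow(truth1)), function(r)
    grid$nodes$pillar_id[which.min((grid$nodes$rest_x_um -
                                    truth1$rest_x_um[r])^2 +
                                   (grid$nodes$rest_y_um -
                                    truth1$rest_y_um[r])^2)], numeric(1))
  cls$is_reference[cls$pillar_id %in% defl_nodes] <- FALSE
  cls$under_cell[cls$pillar_id %in% defl_nodes] <- TRUE
  field <- correct_drift(set_pillar_classes(field, cls))
  ff <- suppressMessages(compute_forces(field, geom24))
  expect_identical(attr(ff, "stiffness_source"), "override")
  top <- sort(ff$f_mag_nN, decreasing = TRUE)[1:2]
  expect_equal(round(top, 1), c(8.5, 5.2), tolerance = 1e-8)
  expect_equal(ff$fx_nN, 24.2 * ff$cx_um)
  # zero displacement -> zero force
  expect_true(all(abs(ff$f_mag_nN[ff$cx_um == 0 & ff$cy_um == 0]) == 0))
})

test_that("per-cell aggregation matches a brute-force loop over the field", {
  bench <- tfm_recovery_benchmark(seed = 2, n_frames = 3L,
                                  drift_per_frame = c(0, 0))
  agg <- aggregate_cell_forces(bench$field)
  sub <- bench$field[bench$field$under_cell & bench$field$tracked, ]
  for (t in unique(sub$frame)) {
    rows <- sub[sub$frame == t, ]
    pf <- agg$per_frame[agg$per_frame$frame == t, ]
    expect_equal(pf$n_pillars, nrow(rows))
    expect_equal(pf$total_force_nN, sum(rows$f_mag_nN))
    expect_equal(pf$mean_force_nN, mean(rows$f_mag_nN))
    expect_equal(pf$mean_displacement_um,
                 mean(sqrt(rows$cx_um^2 + rows$cy_um^2)))
  }
  # additivity: n pillars at equal force sum to n times that force
  fake <- bench$field
  fake$f_mag_nN[fake$under_cell & fake$tracked] <- 1
  agg1 <- aggregate_cell_forces(fake)
  expect_equal(agg1$per_frame$total_force_nN, agg1$per_frame$n_pillars)
})

test_that("doubling planted deflections doubles recovered forces", {
  b1 <- tfm_recovery_benchmark(seed = 6, n_frames = 2L,
                               drift_per_frame = c(0, 0),
                               deflection_range_um = c(0.1, 0.2))
  b2 <- tfm_recovery_benchmark(seed = 6, n_frames = 2L,
                               drift_per_frame = c(0, 0),
                               deflection_range_um = c(0.2, 0.4))
  # same seed draws the same pillars and unit directions; magnitudes double
  ratio <- b2$per_pillar$recovered_force_nN / b1$per_pillar$recovered_force_nN
  expect_equal(ratio, rep(2, length(ratio)), tolerance = 0.05)
})
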