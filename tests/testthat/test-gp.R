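test_that("GP formula evaluates hand-checked pixel values", {
  pair <- ratiometric_pair(matrix(c(100, 100, 100), 1),
                           matrix(c(100, 0, 300), 1))
  map <- compute_gp_map(pair, intensity_threshold = 0)
  expect_equal(as.vector(map$gp), c(0, 1, -0.5))
})

test_that("GP values stay in [-1, 1] for any non-negative channels", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      I420 <- matrix(rexp(400, 1 / 50), 20)
      I473 <- matrix(rexp(400, 1 / 50), 20)
      map <- compute_gp_map(ratiometric_pair(I420, I473),
                            intensity_threshold = 0)
      v <- map$gp[map$mask]
      expect_true(all(v >= -1 & v <= 1))
    }
  })
})

test_that("shape mismatch and all-masked images raise errors", {
  expect_error(ratiometric_pair(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "cellmech_shape_error")
  pair <- ratiometric_pair(matrix(1, 4, 4), matrix(1, 4, 4))
  expect_error(compute_gp_map(pair, intensity_threshold = 10),
               class = "cellmech_empty_mask")
})

test_that("zero-noise laurdan scenes invert exactly on dyadic GP fields", {
  gp_true <- dyadic_gp_field(120, 120, seed = 11)
  sc <- simulate_laurdan_cell(laurdan_scene_spec(gp_true, 256))
  map <- compute_gp_map(ratiometric_pair(sc$I420, sc$I473),
                        intensity_threshold = 0)
  expect_identical(max(abs(map$gp[map$mask] - gp_true[map$mask])), 0)
})

test_that("frequency distributions are normalized with correct bin placement", {
  const <- compute_gp_map(ratiometric_pair(matrix(130, 10, 10),
                                           matrix(70, 10, 10)),
                          intensity_threshold = 0) # GP = 0.3 everywhere
  d <- gp_frequency_distribution(const, 100)
  expect_equal(sum(d$frequencies), 1, tolerance = 1e-9)
  nz <- which(d$frequencies > 0)
  expect_length(nz, 1L)
  expect_lt(abs(d$bin_centers[nz] - 0.3), 0.01 + 1e-12)
  expect_equal(d$n_pixels, 100L)
  # 50/50 two-domain map -> two bins at 0.5 each
  f <- matrix(rep(c(0.625, -0.375), each = 50), 10, 10)
  sc <- simulate_laurdan_cell(laurdan_scene_spec(f, 256))
  d2 <- gp_frequency_distribution(
    compute_gp_map(ratiometric_pair(sc$I420, sc$I473),
                   intensity_threshold = 0), 100)
  expect_equal(sort(d2$frequencies[d2$frequencies > 0]), c(0.5, 0.5))
  expect_error(gp_frequency_distribution(const, 1),
               class = "cellmech_spec_error")
})

test_that("Gaussian fit recovers planted histogram parameters", {
  withr::with_seed(21, {
    g <- matrix(pmin(pmax(rnorm(1e5, 0.3, 0.1), -1), 1), 250, 400)
  })
  sc <- simulate_laurdan_cell(laurdan_scene_spec(g, 200))
  d <- fit_gaussian(gp_frequency_distribution(
    compute_gp_map(ratiometric_pair(sc$I420, sc$I473),
                   intensity_threshold = 0), 100))
  fit <- d$gaussian_fit
  expect_true(fit$converged)
  expect_lt(abs(fit$mean - 0.3), 0.01)
  expect_lt(abs(fit$sd - 0.1), 0.01)
  # exactly Gaussian-shaped noise-free curve -> near-zero residual
  x <- d$bin_centers
  exact <- d
  exact$frequencies <- 0.05 * exp(-(x - 0.2)^2 / (2 * 0.15^2))
  ef <- fit_gaussian(exact)$gaussian_fit
  expect_true(ef$converged)
  expect_lt(ef$residual, 1e-10)
  expect_equal(ef$mean, 0.2, tolerance = 1e-6)
})

test_that("degenerate histograms flag non-convergence instead of zeroing", {
  single <- compute_gp_map(ratiometric_pair(matrix(100, 5, 5),
                                            matrix(100, 5, 5)),
                           intensity_threshold = 0)
  d <- fit_gaussian(gp_frequency_distribution(single, 50))
  expect_false(d$gaussian_fit$converged)
  expect_true(is.na(d$gaussian_fit$mean))
})

test_that("difference curves subtract elementwise, sum to zero and antisymmetrize", {
  gp_a <- dyadic_gp_field(40, 40, seed = 1)
  gp_b <- dyadic_gp_field(40, 40, seed = 2)
  mk <- function(g) gp_frequency_distribution(
    compute_gp_map(ratiometric_pair(
      simulate_laurdan_cell(laurdan_scene_spec(g, 256))$I420,
      simulate_laurdan_cell(laurdan_scene_spec(g, 256))$I473),
      intensity_threshold = 0), 80)
  da <- mk(gp_a); db <- mk(gp_b)
  dc <- gp_difference_curve(da, db)
  expect_equal(dc$delta_frequency, da$frequencies - db$frequencies)
  expect_equal(sum(dc$delta_frequency), 0, tolerance = 1e-9)
  expect_equal(gp_difference_curve(db, da)$delta_frequency,
               -dc$delta_frequency)
  self <- gp_difference_curve(da, da)
  expect_true(all(self$delta_frequency == 0))
  d_short <- gp_frequency_distribution(
    compute_gp_map(ratiometric_pair(matrix(100, 4, 4), matrix(50, 4, 4)),
                   intensity_threshold = 0), 40)
  expect_error(gp_difference_curve(da, d_short),
               class = "cellmech_shape_error")
})

test_that("total mean GP equals the brute-force pixel mean and the binned mean", {
  gp_true <- dyadic_gp_field(60, 60, seed = 7)
  sc <- simulate_laurdan_cell(laurdan_scene_spec(gp_true, 256))
  map <- compute_gp_map(ratiometric_pair(sc$I420, sc$I473),
                        intensity_threshold = 0)
  # brute-force loop oracle
  acc <- 0; n <- 0
  for (i in seq_len(nrow(map$gp))) for (j in seq_len(ncol(map$gp)))
    if (map$mask[i, j]) { acc <- acc + map$gp[i, j]; n <- n + 1 }
  expect_equal(total_mean_gp(map), acc / n)
  d <- gp_frequency_distribution(map, 100)
  expect_lt(abs(total_mean_gp(map) - sum(d$bin_centers * d$frequencies)),
            0.01) # half a bin width
})

test_that("high-GP colocalization matches construction oracles", {
  gp <- two_domain_field(50, 50, hi = 0.8, lo = -0.5, radius_px = 12)
  sc <- simulate_laurdan_cell(laurdan_scene_spec(gp, 256))
  map <- compute_gp_map(ratiometric_pair(sc$I420, sc$I473),
                        intensity_threshold = 0)
  high <- map$gp > 0.5
  np_same <- matrix(0, 50, 50); np_same[high] <- 100
  expect_equal(high_gp_colocalization(map, np_same, 0.5, 50), 1)
  np_disjoint <- matrix(0, 50, 50); np_disjoint[!high] <- 100
  expect_equal(high_gp_colocalization(map, np_disjoint, 0.5, 50), 0)
  # planted 70% overlap
  withr::with_seed(3, {
    idx <- which(high)
    on <- sample(idx, round(0.7 * length(idx)))
    np <- matrix(0, 50, 50); np[on] <- 100
    expect_equal(high_gp_colocalization(map, np, 0.5, 50),
                 length(on) / length(idx))
  })
  expect_warning(res <- high_gp_colocalization(map, np_same, 0.99, 50))
  expect_true(is.nan(res))
})
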