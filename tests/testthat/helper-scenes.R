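# Shared fixture builders (all fixtures generated in code).

noiseless <- list(poisson = FALSE, read_sd = 0)

# GP fields quantized to 1/256 with power-of-two total intensity: channel
# construction and the ratio are then exact in binary floating point.
dyadic_gp_field <- function(ny, nx, seed = 1) {
  withr::with_seed(seed, matrix(round(runif(ny * nx, -1, 1) * 256) / 256,
                                ny, nx))
}

small_pillar_spec <- function(..., seed = 1) {
  pillar_scene_spec(image_shape = c(200L, 200L), pixel_size = 0.1,
                    noise = noiseless, seed = seed, ...)
}

# two-domain mask: disk of GP hi inside, lo outside
two_domain_field <- function(ny, nx, hi, lo, radius_px) {
  f <- matrix(lo, ny, nx)
  f[disk_mask(c(ny, nx), radius_px, 1)] <- hi
  f
}
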