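mono_cube <- function(tau, n_bins = 256, rep_period = 12.5,
                      shape = c(4, 4), counts = 1e4) {
  generate_decay_cube(decay_spec(
    image_shape = shape, tau_short = tau * 0.99999, tau_long = tau,
    f_long_map = 1, n_bins = n_bins, rep_period = rep_period,
    total_counts = counts, poisson = FALSE, seed = 1))$cube
}

test_that("phasor transform matches the mono-exponential closed form", {
  rep_period <- 12.5
  omega <- 2 * pi / rep_period
  # omega * tau = 1  ->  (G, S) = (0.5, 0.5)
  tau1 <- 1 / omega
  ph <- phasor_transform(mono_cube(tau1), min_photons = 1)
  expect_equal(ph$G[1, 1], 0.5, tolerance = 1e-3)
  expect_equal(ph$S[1, 1], 0.5, tolerance = 1e-3)
  # tau -> 0 limit approaches (1, 0)
  ph0 <- phasor_transform(mono_cube(0.01), min_photons = 1)
  expect_equal(ph0$G[1, 1], 1, tolerance = 5e-3)
  expect_equal(ph0$S[1, 1], 0, tolerance = 5e-2)
  # any mono-exponential sits on the universal semicircle within 1e-3
  for (tau in c(0.4, 1.0, 3.0, 6.0)) {
    p <- phasor_transform(mono_cube(tau), min_photons = 1)
    expect_lt(abs((p$G[1, 1] - 0.5)^2 + p$S[1, 1]^2 - 0.25), 1e-3)
  }
  # intensity-scale invariance
  cb <- mono_cube(3.0)
  cb2 <- decay_cube(cb$counts * 5, cb$bin_width, cb$rep_period,
                    poisson = FALSE)
  pa <- phasor_transform(cb, min_photons = 1)
  pb <- phasor_transform(cb2, min_photons = 1)
  expect_equal(pa$G, pb$G, tolerance = 1e-12)
  expect_equal(pa$S, pb$S, tolerance = 1e-12)
})

test_that("min_photons gates validity and an all-dim cube errors", {
  cube <- generate_decay_cube(decay_spec(image_shape = c(4, 4),
                                         total_counts = 3, seed = 2))$cube
  expect_error(phasor_transform(cube, min_photons = 1e5), "below min_photons")
})

test_that("lifetime line fit recovers both components within 10%", {
  spec <- decay_spec(image_shape = c(32, 32),
                     f_long_map = matrix(runif(1024, 0.1, 0.9), 32, 32),
                     total_counts = 1e4, seed = 3)
  cube <- generate_decay_cube(spec)$cube
  ph <- phasor_transform(cube, min_photons = 100)
  line <- fit_lifetime_line(ph)
  expect_lt(abs(line$tau_short - spec$tau_short) / spec$tau_short, 0.1)
  expect_lt(abs(line$tau_long - spec$tau_long) / spec$tau_long, 0.1)
  # noise-free collinear mixtures: line passes through both mono phasors
  nf <- generate_decay_cube(decay_spec(
    image_shape = c(10, 10), f_long_map = matrix(seq(0.1, 0.9, length.out = 100), 10),
    n_bins = 512, total_counts = 1e6, poisson = FALSE, seed = 4))$cube
  phn <- phasor_transform(nf, min_photons = 1)
  ln <- fit_lifetime_line(phn)
  omega <- phn$omega
  expect_equal(unname(ln$p_short), unname(mono_phasor(0.4, omega)),
               tolerance = 1e-3)
  expect_equal(unname(ln$p_long), unname(mono_phasor(3.0, omega)),
               tolerance = 1e-3)
})

test_that("isotropic clouds are rejected as having no dominant axis", {
  set.seed(5)
  ph <- structure(list(G = matrix(rnorm(400, 0.5, 0.01), 20),
                       S = matrix(rnorm(400, 0.3, 0.01), 20),
                       valid = matrix(TRUE, 20, 20),
                       photons = matrix(1e4, 20, 20),
                       omega = 2 * pi / 12.5, harmonic = 1L),
                  class = "phasor_field")
  expect_error(fit_lifetime_line(ph), "no dominant axis")
})

test_that("LLIF endpoints, mixture midpoint and per-pixel recovery", {
  f_map <- matrix(rep(c(0, 0.5, 1), length.out = 144), 12, 12)
  gen <- generate_decay_cube(decay_spec(
    image_shape = c(12, 12), f_long_map = f_map, n_bins = 512,
    total_counts = 1e6, poisson = FALSE, seed = 6))
  ph <- phasor_transform(gen$cube, min_photons = 1)
  line <- fit_lifetime_line(ph)
  lm_ <- llif_map(ph, line)
  expect_equal(lm_$llif[f_map == 1], rep(1, sum(f_map == 1)), tolerance = 1e-3)
  expect_equal(lm_$llif[f_map == 0], rep(0, sum(f_map == 0)), tolerance = 1e-3)
  expect_equal(lm_$llif[f_map == 0.5], rep(0.5, sum(f_map == 0.5)),
               tolerance = 1e-3)
  expect_lt(lm_$clipped_fraction, 0.01)
  # noisy recovery: mean |llif - f_long| <= 0.05 at >= 1e4 photons/pixel
  for (f in c(0.2, 0.5, 0.8)) {
    spec <- decay_spec(image_shape = c(24, 24), f_long_map = f,
                       total_counts = 1e4, seed = round(100 * f))
    gen2 <- generate_decay_cube(spec)
    ph2 <- phasor_transform(gen2$cube, min_photons = 100)
    cal <- generate_decay_cube(decay_spec(
      image_shape = c(24, 24),
      f_long_map = matrix(runif(576, 0.05, 0.95), 24), total_counts = 1e4,
      seed = 7))
    ph_cal <- phasor_transform(cal$cube, min_photons = 100)
    line2 <- fit_lifetime_line(ph_cal)
    lm2 <- llif_map(ph2, line2)
    expect_lte(mean(abs(lm2$llif[ph2$valid] - f)), 0.05)
  }
})
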