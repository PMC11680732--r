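test_that("parameter draws are reproducible and respect their ranges", {
  cfg <- study_config(n_draws = 8, seed = 5)
  d1 <- draw_parameters(cfg)
  d2 <- draw_parameters(cfg)
  expect_identical(d1[, 1:10], d2[, 1:10])
  # degenerate ranges produce constants
  cfg0 <- study_config(ranges = list(glu_mM = c(6.5, 6.5)), n_draws = 4,
                       seed = 5)
  expect_equal(unique(draw_parameters(cfg0, build_systems = FALSE)$glu_mM),
               6.5)
  # distributional check at large n
  cfgN <- study_config(n_draws = 1e4, seed = 6)
  dN <- draw_parameters(cfgN, build_systems = FALSE)
  for (nm in c("glu_mM", "f_mt", "kex_mt_hz", "db0_ppm")) {
    r <- cfgN$ranges[[switch(nm, glu_mM = "glu_mM", f_mt = "f_mt",
                             kex_mt_hz = "kex_mt_hz", db0_ppm = "db0_ppm")]]
    x <- dN[[nm]]
    expect_gte(min(x), r[1]); expect_lte(max(x), r[2])
    se <- diff(r) / sqrt(12) / sqrt(length(x))
    expect_lt(abs(mean(x) - mean(r)), 3 * se)
  }
  expect_error(study_config(ranges = list(glu_mM = c(5, 4))), "ranges")
})

test_that("Rician corruption has the expected magnitude statistics", {
  off <- seq_len(1e5) * 1e-4
  z0 <- zspectrum(off, rep(0, 1e5))
  set.seed(11)
  zn <- add_rician_noise(z0, 0.02)
  # zero signal: Rayleigh mean sigma*sqrt(pi/2)
  expect_equal(mean(zn$z), 0.02 * sqrt(pi / 2), tolerance = 0.02)
  # high signal-to-noise: mean ~ z + sigma^2/(2z)
  zh <- zspectrum(off, rep(0.8, 1e5))
  set.seed(12)
  znh <- add_rician_noise(zh, 0.02)
  expect_equal(mean(znh$z), 0.8 + 0.02^2 / (2 * 0.8), tolerance = 1e-3)
  # sigma = 0 is the identity
  expect_identical(add_rician_noise(zh, 0)$z, zh$z)
})

test_that("the recovery study is unbiased when truth sits at the inits", {
  cfg <- study_config(
    ranges = list(t1w_s = c(1.95, 1.95), t2w_s = c(31.7e-3, 31.7e-3),
                  glu_mM = c(6.5, 6.5), f_guan = c(0.004, 0.004),
                  f_oh = c(0.005, 0.005), f_noe = c(0.041, 0.041),
                  f_mt = c(0.104, 0.104), kex_mt_hz = c(13.3, 13.3),
                  db0_ppm = c(0, 0)),
    n_draws = 2, noise_levels = 0, seed = 9)
  st <- accuracy_precision_study(cfg)
  expect_lt(max(abs(st$draws$rel_err_pct)), 0.2)
})

test_that("error dispersion grows with the noise level", {
  cfg <- study_config(n_draws = 6, noise_levels = c(0, 0.01), seed = 13)
  st <- accuracy_precision_study(cfg)
  s <- st$summary[order(st$summary$sigma), ]
  expect_lt(s$sd_err_pct[1], s$sd_err_pct[2])
})

test_that("noiseless robustness reproduces the exchange-rate error window", {
  # sweeping the generating glutamate exchange rate over the calibration
  # window with the model fixed at 1301 Hz: the concentration error is
  # minimized at the calibrated value and stays bounded (about ten percent)
  # at the window edges
  cfg <- study_config(n_draws = 3, noise_levels = 0, seed = 23)
  rb <- robustness_study("Glu", c(800, 1301, 1850), n_per_value = 3,
                         kex_model_hz = 1301, config = cfg, sigma = 0,
                         multistart = 3, basin_hops = 3)
  expect_true(all(rb$mean_abs_err_pct <= 15))
  expect_equal(which.min(rb$mean_abs_err_pct), 2L)
  expect_lt(rb$mean_abs_err_pct[2], 2)
  expect_error(robustness_study("Glu", numeric()), "non-empty")
})

test_that("phantoms are deterministic and internally consistent", {
  p1 <- make_phantom(nx = 6, ny = 6, nslice = 1, sigma = 0.005, seed = 7)
  p2 <- make_phantom(nx = 6, ny = 6, nslice = 1, sigma = 0.005, seed = 7)
  expect_identical(p1$stack$data, p2$stack$data)
  expect_identical(p1$stack$wassr, p2$stack$wassr)
  # zero noise, constant truth: all in-region voxel spectra identical
  p0 <- make_phantom(nx = 6, ny = 6, nslice = 1, glu_gm_mM = 9, sigma = 0,
                     seed = 7, with_wassr = FALSE)
  gm <- which(p0$stack$masks$brain & !p0$stack$masks$corpus_callosum &
                !p0$stack$masks$ventricle, arr.ind = TRUE)
  ref <- p0$stack$data[gm[1, 1], gm[1, 2], 1, ]
  for (r in seq_len(nrow(gm)))
    expect_identical(p0$stack$data[gm[r, 1], gm[r, 2], 1, ], ref)
})
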