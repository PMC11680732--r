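test_that("multi-subject calibration recovers the generating exchange rate", {
  sc <- default_scheme()
  glu <- c(6.0, 6.3, 6.5, 6.8, 7.0)
  zs <- lapply(glu, function(g)
    simulate_zspectrum(striatum_system(glu_mM = g, kex_glu_hz = 1301), sc))
  pairs <- tibble::tibble(zspec = zs, glu_mM = glu, h2o_mM = 46100)
  cal <- calibrate_kex_glu(pairs, striatum_system(), sc)
  expect_equal(cal$n_used, 5L)
  expect_lt(abs(cal$kex_mean_hz - 1301) / 1301, 0.01)
  expect_true(all(c("subject", "kex_hz", "ci95_hz") %in% names(tidy(cal))))
  expect_equal(glance(cal)$n_total, 5L)
})

test_that("off-calibration exchange rates are recovered too", {
  sc <- default_scheme()
  z <- simulate_zspectrum(striatum_system(kex_glu_hz = 5000), sc)
  pairs <- tibble::tibble(zspec = list(z), glu_mM = 6.5, h2o_mM = 46100)
  cal <- calibrate_kex_glu(pairs, striatum_system(), sc)
  expect_lt(abs(cal$kex_mean_hz - 5000) / 5000, 0.02)
})

test_that("non-informative spectra are flagged and excluded", {
  sc <- default_scheme()
  zflat <- zspectrum(sc$offsets_ppm, rep(1, 51))
  zgood <- striatum_zspec()
  pairs <- tibble::tibble(zspec = list(zgood, zflat), glu_mM = c(6.5, 6.5),
                          h2o_mM = 46100)
  cal <- suppressWarnings(calibrate_kex_glu(pairs, striatum_system(), sc))
  expect_false(cal$subjects$informative[2])
  expect_equal(cal$n_used, 1L)
  expect_error(calibrate_kex_glu(pairs[0, ], striatum_system(), sc), "pair")
})

test_that("glutamate quantification round-trips a noiseless spectrum", {
  sc <- default_scheme()
  q <- quantify_glu(striatum_zspec(), kex_fixed_hz = 1301, h2o_mM = 46100,
                    scheme = sc)
  expect_lt(abs(q$glu_mM - 6.5) / 6.5, 0.01)
  expect_true(q$reliable)
  # a glutamate-free spectrum quantifies to (nearly) zero
  z0 <- simulate_zspectrum(striatum_system(glu_mM = 0), sc)
  q0 <- quantify_glu(z0, 1301, 46100, scheme = sc)
  expect_lt(q0$glu_mM, 0.2)
  expect_error(quantify_glu(striatum_zspec(), kex_fixed_hz = 0), "kex")
})

test_that("exchange-rate mismatch biases concentration consistently", {
  # generated fast (3500 Hz), fitted with the calibrated 1301 Hz: the
  # labeling efficiency mismatch must underestimate [Glu], by the same
  # amount the robustness sweep reports at that grid point
  sc <- default_scheme()
  z <- simulate_zspectrum(striatum_system(kex_glu_hz = 3500), sc)
  q <- quantify_glu(z, kex_fixed_hz = 1301, h2o_mM = 46100, scheme = sc)
  err <- (q$glu_mM - 6.5) / 6.5
  expect_lt(err, -0.10)
  expect_gt(err, -0.60)
  cfg <- study_config(
    ranges = list(t1w_s = c(1.95, 1.95), t2w_s = c(31.7e-3, 31.7e-3),
                  glu_mM = c(6.5, 6.5), f_guan = c(0.004, 0.004),
                  f_oh = c(0.005, 0.005), f_noe = c(0.041, 0.041),
                  f_mt = c(0.104, 0.104), kex_mt_hz = c(13.3, 13.3),
                  db0_ppm = c(0, 0)),
    n_draws = 2, noise_levels = 0, seed = 5)
  rb <- robustness_study("Glu", 3500, n_per_value = 2, kex_model_hz = 1301,
                         config = cfg, sigma = 0, multistart = 1,
                         basin_hops = 0)
  expect_equal(rb$mean_err_pct / 100, err, tolerance = 0.02)
})
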