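gaussian_dip <- function(off, center = 0, depth = 0.9, width = 0.25) {
  1 - depth * exp(-(off - center)^2 / (2 * width^2))
}

test_that("CSF correction is the exact inverse of the forward mix", {
  sc <- default_scheme()
  z_tis <- memo("cc_z", simulate_zspectrum(corpus_callosum_system(), sc))
  z_csf <- zspectrum(sc$offsets_ppm, gaussian_dip(sc$offsets_ppm, width = 0.4))
  pars <- csf_params(f_csf = 0.075, h2o_csf_M = 55.5, h2o_tissue_M = 40.0,
                     t2_csf_s = 110e-3, t2_tissue_s = 28.8e-3, te_s = 25e-3)
  mixed <- csf_mix(z_tis, z_csf, pars)
  rec <- csf_correct(mixed, z_csf, pars)
  expect_lt(max(abs(rec$z - z_tis$z)), 1e-6)
})

test_that("CSF correction degenerates correctly", {
  off <- seq(-5, 5, 0.2)
  z <- zspectrum(off, gaussian_dip(off))
  # zero CSF fraction: identity
  p0 <- csf_params(f_csf = 0)
  expect_equal(csf_correct(z, zspectrum(off, rep(0.8, length(off))), p0)$z,
               z$z)
  # CSF spectrum equal to the measured one: fixed point for any parameters
  p <- csf_params(f_csf = 0.3)
  expect_equal(csf_correct(z, z, p)$z, z$z, tolerance = 1e-12)
  expect_error(csf_params(f_csf = 1), "f_csf")
  expect_error(csf_correct(z, zspectrum(off + 0.05, z$z), p,
                           interpolate = FALSE), "interpolate")
})

test_that("WASSR shift estimation finds displaced dips", {
  off <- seq(-1, 1, 0.1)
  # centered dip: zero shift
  expect_equal(wassr_b0_shift(zspectrum(off, gaussian_dip(off)))$shift_ppm,
               0, tolerance = 1e-9)
  # Lorentzian-like dip displaced by +0.13 ppm
  lor <- function(x, c) 1 - 0.95 / (1 + ((x - c) / 0.18)^2)
  est <- wassr_b0_shift(zspectrum(off, lor(off, 0.13)))
  expect_true(est$reliable)
  expect_lt(abs(est$shift_ppm - 0.13), 0.01)
  # dip at the sweep boundary: flagged unreliable
  expect_warning(b <- wassr_b0_shift(zspectrum(off, lor(off, -0.98))),
                 "boundary")
  expect_false(b$reliable)
})

test_that("B0 re-centering round-trips and matches an unshifted simulation", {
  sc <- default_scheme()
  z <- striatum_zspec()
  expect_identical(apply_b0_shift(z, 0)$z, z$z)
  # +s then -s
  rt <- apply_b0_shift(apply_b0_shift(z, 0.08), -0.08)
  inner <- abs(z$offset_ppm) < 4.5
  expect_lt(max(abs(rt$z[inner] - z$z[inner])), 1e-3)
  # spectrum acquired on a shifted grid, corrected, matches the nominal one
  db0 <- 0.06
  zshift <- simulate_zspectrum(
    striatum_system(), update_scheme(sc, offsets_ppm = sc$offsets_ppm - db0))
  zobs <- zspectrum(sc$offsets_ppm, zshift$z)
  zcorr <- apply_b0_shift(zobs, db0)
  expect_lt(max(abs(zcorr$z[inner] - z$z[inner])), 1e-3)
  expect_error(apply_b0_shift(z, 20), "span")
})

test_that("Rician floor correction inverts its own contamination model", {
  z <- striatum_zspec()
  # a spectrum with no floor is unchanged (floor estimate ~ 0 at 5 uT)
  zc <- rician_floor_correct(z)
  expect_lt(max(abs(zc$z - z$z)), 1e-4)
  expect_equal(zc$z[z$offset_ppm == 0] , 0)
  # constant floor: exact algebraic inverse
  z0 <- 0.05
  zfloor <- zspectrum(z$offset_ppm, z$z * (1 - z0) + z0)
  rec <- rician_floor_correct(zfloor)
  expect_equal(rec$z, rician_floor_correct(z)$z, tolerance = 1e-12)
  # M0 normalization preserved: z = 1 stays 1
  zt <- zspectrum(c(-5, -0.1, 0, 0.1, 5), c(1, 0.1, 0.06, 0.1, 1))
  expect_equal(rician_floor_correct(zt)$z[c(1, 5)], c(1, 1))
  expect_error(rician_floor_correct(zspectrum(c(-0.1, 0, 0.1), c(1, 1, 1))),
               "degenerate")
})

test_that("floor correction reduces error where the noise floor dominates", {
  # the Rician floor biases the deeply saturated region around water; the
  # correction must bring that region closer to truth in most replicates
  z <- striatum_zspec()
  sat <- abs(z$offset_ppm) <= 1
  set.seed(42)
  wins <- 0L
  for (r in 1:100) {
    zn <- add_rician_noise(z, 0.02)
    zc <- rician_floor_correct(zn)
    rmse_raw <- sqrt(mean((zn$z[sat] - z$z[sat])^2))
    rmse_cor <- sqrt(mean((zc$z[sat] - z$z[sat])^2))
    wins <- wins + (rmse_cor < rmse_raw)
  }
  expect_gt(wins, 50)
})
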