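test_that("information criteria follow the least-squares forms", {
  ic <- information_criteria(rss = 51, n_obs = 51, n_free = 1)
  expect_equal(ic$aic, 2)               # n log(1) + 2k
  expect_equal(ic$bic, log(51))
  expect_equal(ic$caic, 2 + 2 * 1 * 2 / 49)
  # hand-computed triple
  rss <- 3.7e-4; n <- 51; k <- 10
  ic <- information_criteria(rss, n, k)
  expect_equal(ic$aic, n * log(rss / n) + 2 * k)
  expect_equal(ic$caic, n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  expect_equal(ic$bic, n * log(rss / n) + k * log(n))
  # penalty monotonicity at equal misfit
  expect_gt(information_criteria(1, 51, 5)$aic,
            information_criteria(1, 51, 3)$aic)
  expect_gt(information_criteria(1, 51, 5)$bic,
            information_criteria(1, 51, 3)$bic)
  expect_error(information_criteria(0, 51, 3), "rss")
  expect_error(information_criteria(1, 4, 3), "n_obs")
})

test_that("a single free fraction is recovered from a noiseless spectrum", {
  sc <- default_scheme()
  z <- striatum_zspec()
  sp <- init_specs_from_system(
    glu_quantification_specs("striatum", kex_hz = 1301, b0_window_ppm = 0),
    striatum_system(), except = "Glu.f_h")
  sp$status[!(sp$name %in% "Glu.f_h")] <- "fixed"
  fit <- fit_zspectrum(z, striatum_system(), sp, sc)
  f_true <- fraction_from_conc(6.5, 46100)
  expect_lt(abs(fit$values[["Glu.f_h"]] - f_true) / f_true, 0.005)
})

test_that("fitting is deterministic", {
  sc <- default_scheme()
  set.seed(3)
  zn <- add_rician_noise(striatum_zspec(), 0.002)
  sp <- init_specs_from_system(glu_quantification_specs("striatum"),
                               striatum_system(), except = "Glu.f_h")
  f1 <- suppressWarnings(fit_zspectrum(zn, striatum_system(), sp, sc,
                                       multistart = 3, seed = 5))
  f2 <- suppressWarnings(fit_zspectrum(zn, striatum_system(), sp, sc,
                                       multistart = 3, seed = 5))
  expect_identical(f1$values, f2$values)
  expect_identical(f1$rss, f2$rss)
})

test_that("a flat spectrum drives CEST fractions to zero and is flagged", {
  sc <- default_scheme()
  zflat <- zspectrum(sc$offsets_ppm, rep(1, 51))
  sp <- glu_quantification_specs("striatum", b0_window_ppm = 0)
  fit <- suppressWarnings(fit_zspectrum(zflat, striatum_system(), sp, sc))
  fr <- c("Guan.f_h", "OH.f_h", "NOE.f_h", "Glu.f_h", "APT.f_h")
  expect_true(all(fit$values[fr] < 1e-4))
  expect_true(any(fit$at_bound[fr]))
})

test_that("confidence intervals shrink with decreasing noise", {
  sc <- default_scheme()
  z <- striatum_zspec()
  ci <- c()
  for (s in c(0.02, 0.01, 0.005, 0)) {
    set.seed(17)
    zn <- if (s > 0) add_rician_noise(z, s) else z
    q <- suppressWarnings(quantify_glu(zn, 1301, 46100, scheme = sc,
                                       multistart = 1))
    ci <- c(ci, q$ci95_mM)
  }
  expect_true(all(diff(ci) < 0))
})

test_that("tidy and glance expose the fit in tabular form", {
  sc <- default_scheme()
  sp <- init_specs_from_system(glu_quantification_specs("striatum"),
                               striatum_system(), except = "Glu.f_h")
  fit <- suppressWarnings(fit_zspectrum(striatum_zspec(), striatum_system(),
                                        sp, sc))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "ci95", "status") %in% names(td)))
  expect_setequal(td$term[td$status == "free"], fit$free)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_lte(gl$r2, 1)
  expect_equal(gl$n_free, length(fit$free))
})

test_that("noiseless parameter recovery holds across random truths", {
  # draws from the study ranges; fits reaching the noise-free floor must
  # reproduce every free parameter to well under 1%
  sc <- default_scheme()
  cfg <- study_config(n_draws = 12, noise_levels = 0, seed = 401)
  draws <- draw_parameters(cfg)
  n_exact <- 0L
  for (i in seq_len(nrow(draws))) {
    z <- simulate_zspectrum(draws$system[[i]], sc)
    q <- suppressWarnings(quantify_glu(z, 1301, 46100, scheme = sc,
                                       multistart = 9, basin_hops = 15,
                                       seed = i))
    fit <- attr(q, "fit")
    if (fit$rss < 1e-10) {
      n_exact <- n_exact + 1L
      truth <- c(
        water.t1_s = draws$t1w_s[i], water.t2_s = draws$t2w_s[i],
        MT.kex_hz = draws$kex_mt_hz[i], MT.f_h = draws$f_mt[i],
        Guan.f_h = draws$f_guan[i], NOE.f_h = draws$f_noe[i],
        Glu.f_h = fraction_from_conc(draws$glu_mM[i], 46100)
      )
      for (nm in names(truth)) {
        if (truth[[nm]] > 1e-4)
          expect_lt(abs(fit$values[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)
      }
    }
  }
  expect_gte(n_exact, 9L)
})
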