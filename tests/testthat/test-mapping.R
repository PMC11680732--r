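test_that("fraction/concentration conversion matches the proton arithmetic", {
  expect_equal(conc_from_fraction(0, 46100), 0)
  f <- fraction_from_conc(6.5, 46100)
  expect_equal(f, 3 * 6.5 / (2 * 46100))
  expect_equal(f, 2.115e-4, tolerance = 1e-3)
  expect_equal(conc_from_fraction(f, 46100), 6.5)
  set.seed(1)
  x <- runif(100, 0, 40)
  expect_equal(conc_from_fraction(fraction_from_conc(x, 40000), 40000), x)
  expect_error(fraction_from_conc(-1, 46100), "conc")
})

test_that("full-rank multilinear truncation is lossless", {
  ph <- memo("phantom_small",
             make_phantom(nx = 8, ny = 8, nslice = 1, glu_gm_mM = 10,
                          sigma = 0, seed = 2, with_wassr = FALSE))
  st <- ph$stack
  d <- dim(st$data)
  out <- mlsvd_denoise(st, core = c(d[1], d[2], d[4]))
  expect_lt(max(abs(out$data - st$data)), 1e-8)
  expect_error(mlsvd_denoise(st, core = c(d[1] + 1, d[2], d[4])), "rank")
})

test_that("low-rank truncation denoises a noisy phantom", {
  ph <- memo("phantom_small",
             make_phantom(nx = 8, ny = 8, nslice = 1, glu_gm_mM = 10,
                          sigma = 0, seed = 2, with_wassr = FALSE))
  clean <- ph$stack
  wins <- 0L
  for (s in 1:10) {
    set.seed(600 + s)
    noisy <- clean
    noisy$data <- clean$data + array(rnorm(length(clean$data), 0, 0.01),
                                     dim(clean$data))
    den <- mlsvd_denoise(noisy, core = c(4, 4, 4))
    wins <- wins + (sqrt(mean((den$data - clean$data)^2)) <
                      sqrt(mean((noisy$data - clean$data)^2)))
  }
  expect_equal(wins, 10L)
})

test_that("discarded multilinear energy equals the reconstruction error", {
  # Parseval identity of the truncated higher-order SVD in the transform
  # domain, checked on a random complex tensor
  set.seed(9)
  x <- array(rnorm(6 * 5 * 7), c(6, 5, 7)) +
    1i * array(rnorm(6 * 5 * 7), c(6, 5, 7))
  xt <- glucest:::hosvd_truncate(x, c(3, 2, 4))
  # projection: error orthogonal to the retained core
  err <- sum(Mod(x - xt)^2)
  expect_equal(sum(Mod(x)^2) - sum(Mod(xt)^2), err, tolerance = 1e-8)
})

test_that("pixel-wise fitting recovers the phantom concentration fields", {
  sc <- default_scheme()
  ph <- make_phantom(nx = 8, ny = 8, nslice = 1, glu_gm_mM = 10,
                     glu_wm_mM = 5.7, sigma = 0, seed = 2)
  maps <- fit_pixelwise(ph$stack, kex_fixed_hz = 1301, scheme = sc)
  gm <- ph$stack$masks$brain & !ph$stack$masks$corpus_callosum &
    !ph$stack$masks$ventricle
  rel <- abs(maps$glu$values[gm] - ph$truth$values[gm]) / ph$truth$values[gm]
  expect_lt(max(rel), 0.01)
  cc <- ph$stack$masks$corpus_callosum
  expect_lt(max(abs(maps$glu$values[cc] - 5.7) / 5.7), 0.01)
  # ventricle: pure water/CSF quantifies to almost zero glutamate
  expect_lt(max(maps$glu$values[ph$stack$masks$ventricle]), 1)
  # out-of-mask voxels carry the non-finite sentinel
  expect_true(all(is.na(maps$glu$values[!ph$stack$masks$brain])))
})

test_that("an empty brain mask yields empty maps without error", {
  ph <- memo("phantom_small",
             make_phantom(nx = 8, ny = 8, nslice = 1, glu_gm_mM = 10,
                          sigma = 0, seed = 2, with_wassr = FALSE))
  st <- ph$stack
  st$masks$brain[] <- FALSE
  maps <- fit_pixelwise(st, kex_fixed_hz = 1301, scheme = default_scheme())
  expect_true(all(is.na(maps$glu$values)))
})

test_that("region statistics summarize ROIs and flag degenerate ones", {
  v <- array(NA_real_, c(4, 4, 1))
  v[1:2, , 1] <- 5          # constant region
  v[3:4, , 1] <- rep(c(8, 10), 4)
  m <- parametric_map(v)
  rois <- list(const = array(c(rep(TRUE, 2), rep(FALSE, 2)), c(4, 4, 1)),
               var = array(c(rep(FALSE, 2), rep(TRUE, 2)), c(4, 4, 1)))
  st <- region_stats(m, rois)
  expect_equal(st$mean[st$roi == "const"], 5)
  expect_equal(st$sd[st$roi == "const"], 0)
  expect_true(is.na(st$mean_over_sd[st$roi == "const"]))
  expect_equal(st$mean[st$roi == "var"], 9)
  out <- array(FALSE, c(4, 4, 1)); out[1, 1, 1] <- FALSE
  bad <- list(outside = array(FALSE, c(4, 4, 1)))
  bad$outside[1, 1, 1] <- TRUE; v2 <- v; v2[1, 1, 1] <- NA
  expect_error(region_stats(parametric_map(v2), bad), "intersect")
})

test_that("stacks round-trip through NIfTI + JSON serialization", {
  ph <- make_phantom(nx = 6, ny = 6, nslice = 2, glu_gm_mM = 8, sigma = 0,
                     seed = 4)
  tmp <- file.path(tempdir(), "stack_rt")
  write_cest_stack(ph$stack, tmp)
  st2 <- read_cest_stack(tmp)
  expect_equal(st2$data, ph$stack$data, tolerance = 1e-12)
  expect_equal(st2$m0, ph$stack$m0, tolerance = 1e-12)
  expect_equal(st2$wassr, ph$stack$wassr, tolerance = 1e-12)
  expect_identical(st2$masks$brain, ph$stack$masks$brain)
  expect_equal(st2$offsets_ppm, ph$stack$offsets_ppm)
})
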