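#' Fit parameter specifications
#'
#' A fit specification is a tibble with one row per model parameter, naming
#' the parameter as `pool.field` (e.g. `"Glu.kex_hz"`, `"water.t2_s"`,
#' `"MT.delta_ppm"`), its status (`free` or `fixed`), starting value and
#' bounds. `fit_par()` declares a free parameter, `fit_fixed()` a fixed one.
#'
#' @param name Parameter name, `pool.field` with field one of `delta_ppm`,
#'   `kex_hz`, `f_h`, `t1_s`, `t2_s`.
#' @param init Starting value (free) or the single value (fixed).
#' @param lower,upper Bounds for a free parameter; must bracket `init`.
#' @return A one-row tibble.
#' @export
fit_par <- function(name, init, lower, upper) {
  if (!(lower <= init && init <= upper))
    abort(sprintf("bounds must satisfy lower <= init <= upper for '%s'.", name))
  tibble(name = name, status = "free", init = init,
         lower = lower, upper = upper)
}

#' @rdname fit_par
#' @param value Fixed value.
#' @export
fit_fixed <- function(name, value) {
  tibble(name = name, status = "fixed", init = value,
         lower = value, upper = value)
}

#' Standard free-parameter set for in vivo Z-spectrum fitting
#'
#' The conventional bounded parameterization for the six-pool brain model:
#' water T1/T2 free within +/-10% of the regional measured values, the MT
#' resonance offset free in [-2.5, 0] ppm, MT exchange rate in [10, 60] Hz,
#' MT fraction in [0, 50%], and the proton fractions of Guan, APT, OH and NOE
#' free from zero up to their conventional upper bounds. The glutamate pool
#' is *not* included here: add it with [glu_calibration_specs()] (f_H fixed
#' from MRS, k_ex free) or [glu_quantification_specs()] (k_ex fixed, f_H
#' free), depending on the task.
#'
#' @param region `"striatum"` (gray matter) or `"corpus_callosum"` (white
#'   matter): selects the water T1/T2 initial values.
#' @return A fit-specification tibble.
#' @export
table_fit_specs <- function(region = c("striatum", "corpus_callosum")) {
  region <- match.arg(region)
  t1w <- if (region == "striatum") 1.95 else 1.85
  t2w <- if (region == "striatum") 31.7e-3 else 28.8e-3
  dplyr::bind_rows(
    fit_par("water.t1_s", t1w, 0.9 * t1w, 1.1 * t1w),
    fit_par("water.t2_s", t2w, 0.9 * t2w, 1.1 * t2w),
    fit_par("MT.delta_ppm", -2.34, -2.5, 0),
    fit_par("MT.kex_hz", 20, 10, 60),
    fit_par("MT.f_h", 0.05, 0, 0.5),
    fit_par("Guan.f_h", 7e-4, 0, 0.022),
    fit_par("APT.f_h", 2e-3, 0, 0.10),
    fit_par("OH.f_h", 3e-4, 0, 0.006),
    fit_par("NOE.f_h", 5e-3, 0, 0.08)
  )
}

#' @rdname table_fit_specs
#' @param glu_mM MRS-measured glutamate concentration (mM), held fixed while
#'   the exchange rate is estimated.
#' @param h2o_mM Regional water concentration (mM).
#' @export
glu_calibration_specs <- function(region = "striatum", glu_mM = 6.5,
                                  h2o_mM = 46100) {
  dplyr::bind_rows(
    table_fit_specs(region),
    fit_par("Glu.kex_hz", 8000, 0, 20000),
    fit_fixed("Glu.f_h", fraction_from_conc(glu_mM, h2o_mM))
  )
}

#' @rdname table_fit_specs
#' @param kex_hz Calibrated glutamate exchange rate (Hz), held fixed while
#'   the concentration is estimated.
#' @param glu_max_mM Upper bound of the free glutamate concentration (mM).
#' @param glu_init_mM Starting concentration (mM).
#' @param b0_window_ppm Half-width of the free residual B0-shift parameter
#'   (`b0.shift_ppm`) included in the quantification fit to absorb the
#'   mis-centering left after the WASSR correction, whose parabolic
#'   estimate is only accurate to roughly 0.01 ppm; 0 removes the
#'   parameter.
#' @export
glu_quantification_specs <- function(region = "striatum", kex_hz = 1301,
                                     h2o_mM = 46100, glu_max_mM = 40,
                                     glu_init_mM = 6.5,
                                     b0_window_ppm = 0.05) {
  out <- dplyr::bind_rows(
    table_fit_specs(region),
    fit_fixed("Glu.kex_hz", kex_hz),
    fit_par("Glu.f_h", fraction_from_conc(glu_init_mM, h2o_mM),
            0, fraction_from_conc(glu_max_mM, h2o_mM))
  )
  if (b0_window_ppm > 0)
    out <- dplyr::bind_rows(
      out, fit_par("b0.shift_ppm", 0, -b0_window_ppm, b0_window_ppm))
  out
}

#' Initialize fit specifications at a system's parameter values
#'
#' Replaces the starting value of every free parameter by the corresponding
#' value of `system` (clipped into the bounds), leaving bounds and fixed
#' parameters untouched. Used to start pixel-wise and simulation-study fits
#' at the calibrated regional model rather than at the generic initial
#' values of the in vivo model-determination stage, which sits far from the
#' calibrated optimum for several parameters.
#'
#' @param specs A fit-specification tibble.
#' @param system A pool-system tibble supplying the starting values.
#' @param except Parameter names to leave at their declared inits.
#' @return The updated specification tibble.
#' @export
init_specs_from_system <- function(specs, system, except = character()) {
  pm <- pools_matrix(system)
  for (i in which(specs$status == "free")) {
    nm <- specs$name[i]
    if (nm %in% except) next
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    r <- match(parts[1], system$pool)
    cc <- param_field_col[parts[2]]
    if (is.na(r) || is.na(cc)) next
    specs$init[i] <- min(max(pm[r, cc], specs$lower[i]), specs$upper[i])
  }
  specs
}

# ---------------------------------------------------------------------------
# parameter application onto the solver's pool matrix
# ---------------------------------------------------------------------------
param_field_col <- c(delta_ppm = 1L, kex_hz = 2L, f_h = 3L, t1_s = 4L,
                     t2_s = 5L)

# map "pool.field" names to (row, col) indices of the pool matrix
param_index <- function(system, names) {
  parts <- strsplit(names, ".", fixed = TRUE)
  rows <- integer(length(names)); cols <- integer(length(names))
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 2L)
      abort(sprintf("parameter '%s' is not of the form pool.field.", names[i]))
    r <- match(parts[[i]][1], system$pool)
    if (is.na(r))
      abort(sprintf("parameter '%s' names an unknown pool.", names[i]))
    cc <- param_field_col[parts[[i]][2]]
    if (is.na(cc))
      abort(sprintf("parameter '%s' names an unknown field.", names[i]))
    rows[i] <- r; cols[i] <- cc
  }
  list(rows = rows, cols = cols)
}

# all non-water pools share the water T1 (convention of the six-pool model)
apply_params <- function(pm, idx, values, tie_t1 = TRUE) {
  for (i in seq_along(values)) pm[idx$rows[i], idx$cols[i]] <- values[i]
  if (tie_t1) pm[, 4L] <- pm[1L, 4L]
  pm
}

#' Fit a Z-spectrum with a bounded multi-pool Bloch-McConnell model
#'
#' Minimizes the sum of squared differences between the measured Z-spectrum
#' and the forward simulation, over the free parameters of `specs`, within
#' their bounds, by Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) started at the declared initial values. The fit
#' is deterministic: identical inputs give identical results. 95% confidence
#' half-widths come from the linearized covariance (t-quantile times the
#' standard error from the Jacobian at the solution).
#'
#' By the convention of the six-pool model, every pool's T1 is tied to the
#' water T1 (so freeing `water.t1_s` moves all pools); set `tie_t1 = FALSE`
#' to fit fully independent T1 values.
#'
#' The optimizer works internally in unit-scaled coordinates
#' (`(value - lower)/(upper - lower)`), which keeps the finite-difference
#' Jacobian well conditioned across parameters of very different magnitude
#' (proton fractions ~1e-4 against exchange rates ~1e3). With
#' `multistart > 1`, additional starting points are tried and the solution
#' with the lowest residual sum of squares is kept: first a structured
#' battery over the strongly degenerate water/MT parameters (low/high
#' corners of their bounds), then seeded Latin-hypercube points over all
#' free parameters (deterministic for a fixed `seed`). Extra starts are
#' skipped as soon as a start reaches `rss_good`.
#'
#' When the data have been floor-corrected ([rician_floor_correct()]), the
#' identical transform must be applied to the model curve inside the
#' residual, otherwise the correction's rescaling biases the fit; pass the
#' correction window as `floor_window_ppm` to enable this. A B0 shift
#' estimated by WASSR is handled by evaluating the model on the shifted
#' spectral axis (`b0_shift_ppm`) rather than resampling the data, which
#' avoids interpolation error entirely.
#'
#' @param zspec A Z-spectrum tibble (columns `offset_ppm`, `z`).
#' @param system A pool-system tibble; fixed parameters not named in `specs`
#'   keep the system's values.
#' @param specs A fit-specification tibble ([fit_par()] rows).
#' @param scheme The acquisition [sat_scheme()]; its offsets are replaced by
#'   the spectrum's own offsets, its M0 offset is kept for normalization.
#' @param solver Forward-model solver passed to [simulate_zspectrum()].
#' @param tie_t1 Tie all pool T1 values to the water T1 (default TRUE).
#' @param b0_shift_ppm Water-center displacement of the data (ppm); the
#'   model is evaluated on the correspondingly shifted axis.
#' @param floor_window_ppm When non-NULL, apply the Rician-floor transform
#'   (minimum within this window of 0 ppm, subtract, rescale) to the model
#'   prediction, matching floor-corrected data.
#' @param multistart Number of starting points (1 = the declared inits only).
#' @param basin_hops After multistart, up to this many seeded small
#'   perturbation-and-refit rounds around the incumbent solution (basin
#'   hopping), applied only while the residual stays above `rss_good`.
#' @param seed Seed for the extra Latin-hypercube starts and basin hops.
#' @param rss_good Early-exit residual threshold for multistart.
#' @param control [minpack.lm::nls.lm.control()] list.
#' @return An object of class `zspec_fit`; see [tidy.zspec_fit()],
#'   [glance.zspec_fit()], [autoplot.zspec_fit()].
#' @export
fit_zspectrum <- function(zspec, system, specs, scheme = sat_scheme(),
                          solver = c("analytic", "numeric"), tie_t1 = TRUE,
                          b0_shift_ppm = 0, floor_window_ppm = NULL,
                          multistart = 1L, basin_hops = 0L, seed = 1L,
                          rss_good = 1e-10, control = NULL) {
  solver <- match.arg(solver)
  stopifnot(is_zspec(zspec))
  validate_pool_system(system)
  free <- specs[specs$status == "free", , drop = FALSE]
  fixed <- specs[specs$status == "fixed", , drop = FALSE]
  if (nrow(free) == 0L) abort("at least one free parameter is required.")
  n_obs <- nrow(zspec); n_free <- nrow(free)
  if (n_obs < n_free + 2L)
    abort("too few offsets for the number of free parameters.")
  control <- control %||% minpack.lm::nls.lm.control(
    maxiter = 300, ftol = 1e-12, ptol = 1e-12, gtol = 0,
    maxfev = 20000, epsfcn = 1e-10
  )

  # the pseudo-parameter "b0.shift_ppm" is a free residual water-center
  # shift applied to the whole spectral axis (all pools together), the
  # conventional way to absorb the error left by the WASSR estimate
  is_b0 <- free$name == "b0.shift_ppm"
  b0_free_idx <- which(is_b0)
  if (length(b0_free_idx) > 1L) abort("duplicate b0.shift_ppm parameter.")
  b0_fixed <- fixed$name == "b0.shift_ppm"
  b0_extra <- if (any(b0_fixed)) fixed$init[b0_fixed][1] else 0

  pm0 <- pools_matrix(system)
  idx_fix <- param_index(system, fixed$name[!b0_fixed])
  pm0 <- apply_params(pm0, idx_fix, fixed$init[!b0_fixed], tie_t1 = tie_t1)
  idx_free <- param_index(system, free$name[!is_b0])
  base_offs <- zspec$offset_ppm - b0_shift_ppm - b0_extra
  zdat <- zspec$z
  rec <- if (is.finite(scheme$recovery_s)) scheme$recovery_s else -1
  solver_code <- if (solver == "analytic") 0L else 1L
  in_floor_win <- if (!is.null(floor_window_ppm))
    which(abs(zspec$offset_ppm) <= floor_window_ppm + 1e-9) else integer()
  if (!is.null(floor_window_ppm) && length(in_floor_win) == 0L)
    abort("no offsets inside `floor_window_ppm` around 0 ppm.")

  fwd <- function(p) {
    pm <- apply_params(pm0, idx_free, p[!is_b0], tie_t1 = tie_t1)
    db0 <- if (length(b0_free_idx)) p[b0_free_idx] else 0
    mz <- bm_mz_cpp(c(base_offs - db0, scheme$m0_offset_ppm), pm,
                    scheme$b1_ut, scheme$n_pulses, scheme$pulse_s,
                    scheme$delay_s, rec, scheme$larmor_mhz, solver_code, 1)
    z <- mz[seq_len(n_obs)] / mz[n_obs + 1L]
    if (length(in_floor_win)) {
      z0 <- min(z[in_floor_win])
      z <- (z - z0) / (1 - z0)
    }
    z
  }
  resid_fn <- function(p) fwd(p) - zdat

  # unit-scaled coordinates
  lo <- free$lower; hi <- free$upper; rng <- pmax(hi - lo, 1e-300)
  resid_u <- function(u) resid_fn(lo + u * rng)
  u_init <- (pmin(pmax(free$init, lo), hi) - lo) / rng
  starts <- list(u_init)
  if (multistart > 1L) {
    # the water/MT parameters carry the strongest degeneracies; the first
    # eight extra starts place them at physiologically low/high values
    # (unit-scale quantiles of their bounds; the MT fraction quantiles sit
    # at typical brain values rather than at the loose optimization bound),
    # all other parameters kept at the declared inits. Remaining starts are
    # seeded Latin-hypercube points over all free parameters.
    corner_q <- list(water.t1_s = c(0.1, 0.9), MT.kex_hz = c(0.2, 0.8))
    corner_names <- intersect(names(corner_q), free$name)
    ci <- match(corner_names, free$name)
    n_extra <- multistart - 1L
    corners <- if (length(ci)) {
      g <- expand.grid(corner_q[corner_names])
      lapply(seq_len(nrow(g)), function(r) {
        u <- u_init; u[ci] <- as.numeric(g[r, ]); u
      })
    } else list()
    starts <- c(starts, head(corners, n_extra))
    n_lhs <- n_extra - length(head(corners, n_extra))
    if (n_lhs > 0L) {
      set.seed(seed)
      lhs <- vapply(seq_len(n_free), function(j)
        (sample(n_lhs) - runif(n_lhs)) / n_lhs, numeric(n_lhs))
      lhs <- matrix(lhs, nrow = n_lhs, ncol = n_free)
      for (s in seq_len(n_lhs)) starts[[length(starts) + 1L]] <- lhs[s, ]
    }
  }
  # exploration runs (extra starts, basin hops) only need to localize a
  # basin; they use a capped iteration count, and the winner is polished
  # at full depth afterwards
  explore_control <- control
  explore_control$maxiter <- min(control$maxiter, 50L)
  run_lm <- function(u0, ctl) {
    minpack.lm::nls.lm(par = u0, lower = rep(0, n_free),
                       upper = rep(1, n_free), fn = resid_u, control = ctl)
  }
  # basin hopping around an incumbent: seeded small perturbations escaping
  # the flat shallow valleys that trap plain Levenberg-Marquardt
  hop_phase <- function(fit, n_hops) {
    set.seed(seed + 1299709L)
    for (h in seq_len(n_hops)) {
      if (fit$deviance < rss_good) break
      u0 <- pmin(pmax(as.numeric(fit$par) + rnorm(n_free, 0, 0.08), 0), 1)
      cand <- run_lm(u0, explore_control)
      if (cand$deviance < fit$deviance) fit <- cand
    }
    fit
  }
  fit <- run_lm(starts[[1]], control)
  # hops are cheaper than fresh distant starts and rescue most trapped
  # solutions, so they run first; the structured battery is the fallback
  if (basin_hops > 0L && fit$deviance >= rss_good)
    fit <- hop_phase(fit, basin_hops)
  for (s in seq_along(starts)[-1]) {
    if (fit$deviance < rss_good) break
    cand <- run_lm(starts[[s]], explore_control)
    if (cand$deviance < fit$deviance) fit <- cand
  }
  if (basin_hops > 0L && fit$deviance >= rss_good)
    fit <- hop_phase(fit, basin_hops)
  if (length(starts) > 1L || basin_hops > 0L) {
    polish <- minpack.lm::nls.lm(par = as.numeric(fit$par),
                                 lower = rep(0, n_free),
                                 upper = rep(1, n_free), fn = resid_u,
                                 control = control)
    if (polish$deviance < fit$deviance) fit <- polish
  }
  par <- setNames(lo + as.numeric(fit$par) * rng, free$name)
  res <- resid_fn(par)
  rss <- sum(res^2)
  tss <- sum((zdat - mean(zdat))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  # linearized covariance -> 95% CI half-widths (computed in unit scale,
  # mapped back through the parameter ranges)
  u_par <- (par - lo) / rng
  J <- jacobian_fd(resid_u, u_par, rep(0, n_free), rep(1, n_free))
  ci95 <- rep(NA_real_, n_free)
  se <- rep(NA_real_, n_free)
  dof <- n_obs - n_free
  if (dof > 0 && rss > 0) {
    jtj <- crossprod(J)
    cv <- tryCatch(solve(jtj) * rss / dof, error = function(e) NULL)
    if (!is.null(cv)) {
      se <- sqrt(pmax(diag(cv), 0)) * rng
      ci95 <- qt(0.975, dof) * se
    }
  }
  scale <- pmax(abs(free$upper - free$lower), 1e-12)
  at_lower <- (par - free$lower) < 1e-8 * scale
  at_upper <- (free$upper - par) < 1e-8 * scale
  converged <- fit$info %in% 1:4
  if (!converged)
    warn(sprintf("fit did not converge (nls.lm info %d): returning best-so-far.",
                 fit$info))

  ic <- if (rss > 0) information_criteria(rss, n_obs, n_free) else
    list(aic = -Inf, caic = -Inf, bic = -Inf)

  structure(list(
    values = c(par, setNames(fixed$init, fixed$name)),
    free = free$name,
    ci95 = setNames(ci95, free$name),
    se = setNames(se, free$name),
    at_bound = setNames(at_lower | at_upper, free$name),
    residuals = tibble(offset_ppm = zspec$offset_ppm, z = zdat,
                       fitted = zdat + res, resid = res),
    r2 = r2, rss = rss, n_obs = n_obs, n_free = n_free,
    aic = ic$aic, caic = ic$caic, bic = ic$bic,
    converged = converged, info = fit$info, niter = fit$niter,
    system = system, specs = specs, scheme = scheme, solver = solver,
    tie_t1 = tie_t1
  ), class = "zspec_fit")
}

# forward-difference Jacobian respecting bounds (steps flip direction at the
# upper bound); intended for unit-scaled parameters
jacobian_fd <- function(fn, par, lower, upper, rel = 1e-5) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- max(rel * abs(par[j]), 1e-6)
    if (par[j] + h > upper[j]) h <- -h
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

#' Least-squares information criteria
#'
#' Gaussian least-squares forms used to rank candidate pool models:
#' `AIC = n log(rss/n) + 2k`, `cAIC = AIC + 2k(k+1)/(n-k-1)`,
#' `BIC = n log(rss/n) + k log(n)`, with `k` the number of free parameters
#' (no +1 for the noise variance; only differences between models matter and
#' the constant convention cancels).
#'
#' @param rss Residual sum of squares (> 0).
#' @param n_obs Number of observations.
#' @param n_free Number of free parameters.
#' @return A list with elements `aic`, `caic`, `bic`.
#' @export
information_criteria <- function(rss, n_obs, n_free) {
  if (rss <= 0) abort("`rss` must be > 0.")
  if (n_obs <= n_free + 1) abort("`n_obs` must exceed `n_free` + 1.")
  aic <- n_obs * log(rss / n_obs) + 2 * n_free
  list(
    aic = aic,
    caic = aic + 2 * n_free * (n_free + 1) / (n_obs - n_free - 1),
    bic = n_obs * log(rss / n_obs) + n_free * log(n_obs)
  )
}

#' @export
print.zspec_fit <- function(x, ...) {
  cat("<zspec_fit> ", x$n_free, " free parameters, ", x$n_obs, " offsets\n",
      sep = "")
  cat(sprintf("  R2 = %.6g, RSS = %.4g, AIC = %.4g, cAIC = %.4g, BIC = %.4g\n",
              x$r2, x$rss, x$aic, x$caic, x$bic))
  if (!x$converged) cat("  ! not converged (best-so-far)\n")
  if (any(x$at_bound))
    cat("  ! at bound:", paste(names(which(x$at_bound)), collapse = ", "), "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a Z-spectrum fit
#'
#' @param x A `zspec_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per model parameter with estimate, 95% CI
#'   half-width, standard error, status and bound flag. `glance()`: a one-row
#'   summary with fit-quality statistics and information criteria.
#' @export
tidy.zspec_fit <- function(x, ...) {
  free <- tibble(
    term = x$free, estimate = unname(x$values[x$free]),
    ci95 = unname(x$ci95), std_error = unname(x$se),
    status = "free", at_bound = unname(x$at_bound)
  )
  fixed_names <- setdiff(names(x$values), x$free)
  dplyr::bind_rows(free, tibble(
    term = fixed_names, estimate = unname(x$values[fixed_names]),
    ci95 = NA_real_, std_error = NA_real_, status = "fixed", at_bound = FALSE
  ))
}

#' @rdname tidy.zspec_fit
#' @export
glance.zspec_fit <- function(x, ...) {
  tibble(
    r2 = x$r2, rss = x$rss, n_obs = x$n_obs, n_free = x$n_free,
    aic = x$aic, caic = x$caic, bic = x$bic,
    converged = x$converged, niter = x$niter
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
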