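#' Rank candidate pool models by information criteria
#'
#' Fits every candidate model to the same Z-spectrum and tabulates R2, AIC,
#' corrected AIC and BIC, the layout used to choose the six-pool model
#' (water, MT, Glu, Guan, APT, OH, NOE) for brain data at 5 uT. A fit failure
#' in one candidate is recorded and does not abort the comparison.
#'
#' Candidates are fitted in the given order and warm-started: each model's
#' shared parameters are also tried starting from the best previous
#' candidate's solution, so that nested models are not penalized by
#' optimization failures rather than by genuine lack of fit. When a fit
#' already reaches `rss_good` no further starts are tried.
#'
#' @param zspec The measured (or simulated) Z-spectrum.
#' @param candidates Named list; each element is a list with components
#'   `system` (pool-system tibble) and `specs` (fit-specification tibble).
#'   See [candidate_models()].
#' @param scheme The acquisition [sat_scheme()].
#' @param rss_good Early-exit residual threshold (set it near the expected
#'   noise floor `n * sigma^2` for noisy data).
#' @param warm_chain Warm-start each candidate from the best previous one.
#' @param control [minpack.lm::nls.lm.control()] for the candidate fits.
#'   The default is lighter than [fit_zspectrum()]'s: criterion differences
#'   between models are order one, so residuals resolved to ~1e-9 relative
#'   rank them reliably, and tighter tolerances only let the optimizer
#'   grind on noise.
#' @param ... Passed to [fit_zspectrum()] (e.g. `multistart`,
#'   `floor_window_ppm`).
#' @return A tibble with one row per candidate (columns `model`, `r2`, `rss`,
#'   `n_free`, `aic`, `caic`, `bic`, `converged`, `error` and a `fit`
#'   list-column), with an attribute `best` naming the argmin per criterion.
#' @export
select_model <- function(zspec, candidates, scheme = sat_scheme(),
                         rss_good = 1e-10, warm_chain = TRUE,
                         control = NULL, ...) {
  control <- control %||% minpack.lm::nls.lm.control(
    maxiter = 100, ftol = 1e-9, ptol = 1e-9, gtol = 0,
    maxfev = 2500, epsfcn = 1e-10
  )
  if (length(candidates) < 1L) abort("at least one candidate is required.")
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    abort("`candidates` must be a named list.")
  prev <- list()
  rows <- purrr::imap(candidates, function(cand, nm) {
    sp_list <- list(cand$specs)
    if (warm_chain && length(prev)) {
      pb <- prev[[which.min(vapply(prev, function(f) f$rss, 1))]]
      sp2 <- cand$specs
      for (p in names(pb$values)) {
        i <- which(sp2$name == p & sp2$status == "free")
        if (length(i))
          sp2$init[i] <- min(max(pb$values[[p]], sp2$lower[i]), sp2$upper[i])
      }
      sp_list <- c(list(sp2), sp_list)
    }
    fit <- NULL
    for (sp in sp_list) {
      cand_fit <- tryCatch(
        suppressWarnings(
          fit_zspectrum(zspec, cand$system, sp, scheme,
                        rss_good = rss_good, control = control, ...)
        ),
        error = function(e) e
      )
      if (inherits(cand_fit, "error")) { fit <- fit %||% cand_fit; next }
      if (!inherits(fit, "zspec_fit") || cand_fit$rss < fit$rss)
        fit <- cand_fit
      if (inherits(fit, "zspec_fit") && fit$rss < rss_good) break
    }
    if (inherits(fit, "error") || is.null(fit)) {
      tibble(model = nm, r2 = NA_real_, rss = NA_real_, n_free = NA_integer_,
             aic = NA_real_, caic = NA_real_, bic = NA_real_,
             converged = FALSE,
             error = if (is.null(fit)) "fit failed" else conditionMessage(fit),
             fit = list(NULL))
    } else {
      prev[[nm]] <<- fit
      tibble(model = nm, r2 = fit$r2, rss = fit$rss, n_free = fit$n_free,
             aic = fit$aic, caic = fit$caic, bic = fit$bic,
             converged = fit$converged, error = NA_character_,
             fit = list(fit))
    }
  })
  out <- dplyr::bind_rows(rows)
  best <- lapply(c(aic = "aic", caic = "caic", bic = "bic"), function(cr) {
    v <- out[[cr]]
    if (all(is.na(v))) NA_character_ else out$model[which.min(v)]
  })
  attr(out, "best") <- best
  out
}

#' Standard candidate-model ladder
#'
#' The nested series of candidate models used to identify the pool content of
#' brain Z-spectra at 5 uT, from water + MT up to eight pools (adding Glu,
#' Guan, APT, OH, NOE, and the optional NOE2/Tau pools). The glutamate proton
#' fraction is fixed from the MRS concentration in every candidate that
#' contains Glu, with its exchange rate free.
#'
#' @param region `"striatum"` or `"corpus_callosum"`.
#' @param glu_mM MRS glutamate concentration fixed in the Glu pool (mM).
#' @param h2o_mM Regional water concentration (mM).
#' @return A named list of candidates for [select_model()].
#' @export
candidate_models <- function(region = "striatum", glu_mM = 6.5,
                             h2o_mM = 46100) {
  base <- if (region == "striatum") striatum_system(glu_mM, 1301, h2o_mM)
          else corpus_callosum_system(glu_mM, 1276, h2o_mM)
  t1w <- base$t1_s[1]
  keep <- function(pools) {
    sys <- base[base$pool %in% pools, , drop = FALSE]
    attr(sys, "region") <- attr(base, "region")
    validate_pool_system(sys)
    sys
  }
  spec_for <- function(pools, system) {
    sp <- table_fit_specs(region)
    sp <- sp[vapply(strsplit(sp$name, ".", fixed = TRUE),
                    function(p) p[1] %in% pools, TRUE), , drop = FALSE]
    if ("Glu" %in% pools)
      sp <- dplyr::bind_rows(
        sp,
        fit_par("Glu.kex_hz", 8000, 0, 20000),
        fit_fixed("Glu.f_h", fraction_from_conc(glu_mM, h2o_mM))
      )
    if ("NOE2" %in% pools) sp <- dplyr::bind_rows(sp, fit_par("NOE2.f_h", 5e-3, 0, 0.08))
    if ("Tau" %in% pools) sp <- dplyr::bind_rows(sp, fit_par("Tau.f_h", 3e-4, 0, 3e-3))
    # start at the regional reference model (excluding the exchange rate
    # being estimated), which conditions the nonlinear fit far better than
    # the generic initial values
    init_specs_from_system(sp, system, except = "Glu.kex_hz")
  }
  sets <- list(
    "water+MT" = c("water", "MT"),
    "water+MT+Glu" = c("water", "MT", "Glu"),
    "water+MT+Glu+Guan" = c("water", "MT", "Glu", "Guan"),
    "water+MT+Glu+Guan+APT" = c("water", "MT", "Glu", "Guan", "APT"),
    "water+MT+Glu+Guan+APT+OH" = c("water", "MT", "Glu", "Guan", "APT", "OH"),
    "water+MT+Glu+Guan+APT+OH+NOE" =
      c("water", "MT", "Glu", "Guan", "APT", "OH", "NOE"),
    "water+MT+Glu+Guan+APT+OH+Tau" =
      c("water", "MT", "Glu", "Guan", "APT", "OH", "Tau"),
    "water+MT+Glu+Guan+APT+OH+NOE+NOE2" =
      c("water", "MT", "Glu", "Guan", "APT", "OH", "NOE", "NOE2"),
    "water+MT+Glu+Guan+APT+OH+NOE+Tau" =
      c("water", "MT", "Glu", "Guan", "APT", "OH", "NOE", "Tau")
  )
  lapply(sets, function(pools) {
    sys <- if (any(c("NOE2", "Tau") %in% pools)) {
      extra <- intersect(c("NOE2", "Tau"), pools)
      s <- keep(setdiff(pools, extra))
      for (e in extra) s <- add_pool(s, candidate_pool(e, t1_s = t1w))
      s
    } else keep(pools)
    list(system = sys, specs = spec_for(pools, sys))
  })
}
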