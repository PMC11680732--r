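#' Mono-exponential T2 estimation from multi-echo signals
#'
#' Least-squares fit of `S(TE) = S0 exp(-TE/T2)` to signal amplitudes
#' measured at several echo times, as used to estimate metabolite and water
#' T2 from multi-TE spectroscopy. Starting values come from the log-linear
#' regression; non-decaying data are flagged (no finite T2).
#'
#' @param te_ms Echo times (ms), at least 3 distinct values.
#' @param signal Positive signal amplitudes, same length.
#' @return A one-row tibble: `s0`, `t2_ms`, `r2`, `reliable`.
#' @export
monoexp_t2_fit <- function(te_ms, signal) {
  if (length(te_ms) != length(signal)) abort("inputs must have equal length.")
  if (length(unique(te_ms)) < 3) abort("need >= 3 distinct echo times.")
  if (any(signal <= 0)) abort("signals must be positive.")
  ll <- lm(log(signal) ~ te_ms)
  slope <- coef(ll)[2]
  if (!is.finite(slope) || slope >= 0) {
    warn("non-decaying signal: T2 estimate unreliable.")
    return(tibble(s0 = exp(coef(ll)[1]), t2_ms = Inf, r2 = NA_real_,
                  reliable = FALSE))
  }
  start <- c(s0 = exp(unname(coef(ll)[1])), t2 = -1 / unname(slope))
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = c(0, 1e-3), upper = c(Inf, 1e6),
    fn = function(p) p[1] * exp(-te_ms / p[2]) - signal
  )
  p <- fit$par
  res <- p[1] * exp(-te_ms / p[2]) - signal
  r2 <- 1 - sum(res^2) / sum((signal - mean(signal))^2)
  reliable <- fit$info %in% 1:4 && p[2] < 0.99e6
  if (!reliable) warn("T2 fit unreliable (non-convergent or at bound).")
  tibble(s0 = unname(p[1]), t2_ms = unname(p[2]), r2 = r2,
         reliable = reliable)
}

#' Water-scaled metabolite concentration
#'
#' Standard internal-water-reference quantification: the metabolite signal is
#' scaled by the unsuppressed water signal measured at the same echo time,
#' corrected for the T2 decay of both resonances and for the proton counts
#' (2 for water, `n_protons` for the metabolite):
#' `[M] = (S_met/S_water) * (2/n) * [H2O] * exp(TE/T2_met - TE/T2_water)`,
#' returned in mM. T1 saturation is neglected (long TR). The formula is
#' linear in `s_met` and in `h2o_M`, and exactly inverts the corresponding
#' forward signal model.
#'
#' @param s_met Metabolite signal amplitude at `te_ms`.
#' @param s_water Unsuppressed water signal at `te_ms` (> 0).
#' @param n_protons Protons contributing to the metabolite resonance.
#' @param t2_met_ms,t2_water_ms T2 values (ms).
#' @param te_ms Echo time (ms).
#' @param h2o_M Water concentration in the voxel (M).
#' @return Concentration in mM.
#' @export
water_scaled_concentration <- function(s_met, s_water, n_protons,
                                       t2_met_ms, t2_water_ms, te_ms,
                                       h2o_M) {
  if (any(s_water <= 0)) abort("`s_water` must be > 0.")
  if (any(c(s_met, n_protons, t2_met_ms, t2_water_ms, h2o_M) <= 0) ||
      any(te_ms < 0))
    abort("inputs must be positive (te_ms >= 0).")
  (s_met / s_water) * (2 / n_protons) * h2o_M *
    exp(te_ms / t2_met_ms - te_ms / t2_water_ms) * 1e3
}

#' Packaged MRS calibration values
#'
#' Regional T2 values and metabolite concentrations measured by localized
#' MRS in mouse striatum and corpus callosum, used to fix the glutamate pool
#' during exchange-rate calibration (glutamate: 6.5 mM striatum, 5.7 mM
#' corpus callosum; water T2 31.7 / 28.8 ms).
#'
#' @return A tibble with columns `region`, `species`, `t2_ms`, `t2_sd_ms`,
#'   `conc_mM`, `conc_sd_mM`.
#' @export
mrs_calibration <- function() {
  path <- system.file("extdata", "mrs_calibration.csv", package = "glucest",
                      mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(out)
}
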