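#' Define one proton-exchanging pool
#'
#' A pool is one exchanging species in the Bloch-McConnell model: its chemical
#' shift relative to water, the pseudo-first-order exchange rate of its labile
#' protons toward water, its proton fraction relative to water protons, its
#' relaxation times and its absorption lineshape. The semisolid
#' magnetization-transfer (MT) pool uses a super-Lorentzian lineshape and is
#' treated as a longitudinal-only compartment.
#'
#' @param name Pool label (unique within a system), e.g. `"Glu"`.
#' @param delta_ppm Chemical-shift offset from water (ppm).
#' @param kex_hz Exchange rate toward water (Hz), `>= 0`.
#' @param f_h Proton fraction relative to water protons (dimensionless).
#' @param t1_s Longitudinal relaxation time (s).
#' @param t2_s Transverse relaxation time (s).
#' @param lineshape `"lorentzian"` or `"super_lorentzian"` (MT only).
#' @return A one-row tibble; bind rows of these into a pool system.
#' @seealso [pool_system()], [striatum_system()]
#' @export
pool <- function(name, delta_ppm, kex_hz, f_h, t1_s, t2_s,
                 lineshape = c("lorentzian", "super_lorentzian")) {
  lineshape <- match.arg(lineshape)
  if (f_h < 0) abort("`f_h` must be >= 0.")
  if (kex_hz < 0) abort("`kex_hz` must be >= 0.")
  if (t1_s <= 0 || t2_s <= 0) abort("relaxation times must be > 0.")
  tibble(
    pool = name, delta_ppm = delta_ppm, kex_hz = kex_hz, f_h = f_h,
    t1_s = t1_s, t2_s = t2_s, lineshape = lineshape
  )
}

#' Assemble and validate a pool system
#'
#' A pool system is a tibble with one row per pool, water first. Water must
#' have `delta_ppm = 0`, `f_h = 1` and `kex_hz = 0`; at most one pool may be
#' super-Lorentzian (the MT pool). Exchange is star-shaped: every pool
#' exchanges with water only, with back-rates fixed by detailed balance.
#'
#' @param ... One-row tibbles from [pool()] (water first), or a single
#'   data frame with the pool columns.
#' @param region Optional free-text region label stored as an attribute.
#' @return A validated pool-system tibble.
#' @export
pool_system <- function(..., region = NULL) {
  parts <- list(...)
  sys <- if (length(parts) == 1L && is.data.frame(parts[[1]]) &&
             nrow(parts[[1]]) > 1L) {
    as_tibble(parts[[1]])
  } else {
    dplyr::bind_rows(parts)
  }
  validate_pool_system(sys)
  attr(sys, "region") <- region
  sys
}

#' @rdname pool_system
#' @param system A pool-system tibble to check.
#' @export
validate_pool_system <- function(system) {
  req <- c("pool", "delta_ppm", "kex_hz", "f_h", "t1_s", "t2_s", "lineshape")
  if (!all(req %in% names(system)))
    abort(paste("pool system is missing columns:",
                paste(setdiff(req, names(system)), collapse = ", ")))
  if (anyDuplicated(system$pool)) abort("pool names must be unique.")
  w <- which(system$pool == "water")
  if (length(w) != 1L) abort("exactly one pool must be named 'water'.")
  if (w != 1L) abort("the water pool must come first.")
  if (system$delta_ppm[1] != 0 || system$f_h[1] != 1 || system$kex_hz[1] != 0)
    abort("water must have delta_ppm = 0, f_h = 1, kex_hz = 0.")
  if (sum(system$lineshape == "super_lorentzian") > 1L)
    abort("at most one pool (MT) may be super_lorentzian.")
  if (any(system$f_h < 0) || any(system$kex_hz < 0) ||
      any(system$t1_s <= 0) || any(system$t2_s <= 0))
    abort("invalid pool parameters (negative fraction/rate or non-positive T1/T2).")
  invisible(system)
}

# pools -> numeric matrix consumed by the C++ solver
pools_matrix <- function(system) {
  cbind(
    delta_ppm = system$delta_ppm, kex_hz = system$kex_hz, f_h = system$f_h,
    t1_s = system$t1_s, t2_s = system$t2_s,
    is_mt = as.numeric(system$lineshape == "super_lorentzian")
  )
}

#' Convert between glutamate proton fraction and concentration
#'
#' Glutamate contributes three exchangeable amine protons per molecule while
#' water contributes two, so the proton fraction maps to concentration as
#' `[Glu] = f_h / 3 * 2 * [H2O]`. The two functions are exact inverses.
#'
#' @param f_h Glutamate amine proton fraction (relative to water protons).
#' @param conc_mM Glutamate concentration (mM).
#' @param h2o_mM Regional water concentration (mM), e.g. 46100 in gray matter
#'   and 40000 in corpus callosum.
#' @param n_protons Exchangeable protons per metabolite molecule (3 for the
#'   glutamate amine group).
#' @return Concentration in mM, or a proton fraction.
#' @export
conc_from_fraction <- function(f_h, h2o_mM, n_protons = 3) {
  if (any(f_h < 0)) abort("`f_h` must be >= 0.")
  if (any(h2o_mM <= 0)) abort("`h2o_mM` must be > 0.")
  f_h / n_protons * 2 * h2o_mM
}

#' @rdname conc_from_fraction
#' @export
fraction_from_conc <- function(conc_mM, h2o_mM, n_protons = 3) {
  if (any(conc_mM < 0)) abort("`conc_mM` must be >= 0.")
  if (any(h2o_mM <= 0)) abort("`h2o_mM` must be > 0.")
  n_protons * conc_mM / (2 * h2o_mM)
}

#' Reference six-pool brain models
#'
#' Six-pool systems (water, MT, Glu, Guan, APT, OH, NOE) parameterized at the
#' mean in vivo fitted values for mouse striatum (gray matter) and corpus
#' callosum (white matter) at 11.7 T. Chemical shifts and the fixed exchange
#' rates of the non-Glu pools are literature values (Guan 2.0 ppm / 300 Hz,
#' APT 3.5 ppm / 25 Hz, OH 1.0 ppm / 2000 Hz, NOE -3.5 ppm / 15 Hz);
#' metabolite T2 is 10 ms, MT T2 is 10 us, and all pools share the water T1.
#' The glutamate pool is set from a concentration via [fraction_from_conc()].
#'
#' @param glu_mM Glutamate concentration (mM) used to set the Glu pool.
#' @param kex_glu_hz Glutamate amine exchange rate (Hz).
#' @param h2o_mM Regional water concentration (mM).
#' @return A pool-system tibble.
#' @export
striatum_system <- function(glu_mM = 6.5, kex_glu_hz = 1301,
                            h2o_mM = 46100) {
  t1w <- 1.95
  pool_system(
    pool("water", 0, 0, 1, t1w, 31.7e-3),
    pool("MT", -0.03, 13.3, 0.104, t1w, 10e-6, "super_lorentzian"),
    pool("Glu", 3.0, kex_glu_hz, fraction_from_conc(glu_mM, h2o_mM), t1w, 10e-3),
    pool("Guan", 2.0, 300, 0.004, t1w, 10e-3),
    pool("APT", 3.5, 25, 0.035, t1w, 10e-3),
    pool("OH", 1.0, 2000, 0.005, t1w, 10e-3),
    pool("NOE", -3.5, 15, 0.041, t1w, 10e-3),
    region = "striatum"
  )
}

#' @rdname striatum_system
#' @export
corpus_callosum_system <- function(glu_mM = 5.7, kex_glu_hz = 1276,
                                   h2o_mM = 40000) {
  t1w <- 1.85
  pool_system(
    pool("water", 0, 0, 1, t1w, 28.8e-3),
    pool("MT", -0.53, 25.8, 0.129, t1w, 10e-6, "super_lorentzian"),
    pool("Glu", 3.0, kex_glu_hz, fraction_from_conc(glu_mM, h2o_mM), t1w, 10e-3),
    pool("Guan", 2.0, 300, 0.007, t1w, 10e-3),
    pool("APT", 3.5, 25, 0.044, t1w, 10e-3),
    pool("OH", 1.0, 2000, 0.005, t1w, 10e-3),
    pool("NOE", -3.5, 15, 0.036, t1w, 10e-3),
    region = "corpus_callosum"
  )
}

#' Candidate pools for model selection
#'
#' Extra candidate pools beyond the six-pool model: a second NOE pool at
#' -1.6 ppm (10 Hz) and a fast-exchanging taurine pool at 3.2 ppm
#' (50000 Hz). Use with [add_pool()] to build larger candidate models.
#'
#' @param name `"NOE2"` or `"Tau"`.
#' @param t1_s Longitudinal relaxation (defaults to the water T1 convention).
#' @param f_h Proton fraction (defaults to the fitting initial values).
#' @return A one-row pool tibble.
#' @export
candidate_pool <- function(name = c("NOE2", "Tau"), t1_s = 1.95, f_h = NULL) {
  name <- match.arg(name)
  switch(name,
    NOE2 = pool("NOE2", -1.6, 10, f_h %||% 0.005, t1_s, 10e-3),
    Tau  = pool("Tau", 3.2, 50000, f_h %||% 3e-4, t1_s, 10e-3)
  )
}

#' Add, drop or modify pools in a system
#'
#' @param system A pool-system tibble.
#' @param new A one-row pool tibble from [pool()].
#' @param name Pool name to drop.
#' @return The modified, revalidated system.
#' @export
add_pool <- function(system, new) {
  out <- dplyr::bind_rows(system, new)
  validate_pool_system(out)
  attr(out, "region") <- attr(system, "region")
  out
}

#' @rdname add_pool
#' @export
drop_pool <- function(system, name) {
  if (!name %in% system$pool) abort(paste0("no pool named '", name, "'."))
  out <- system[system$pool != name, , drop = FALSE]
  validate_pool_system(out)
  attr(out, "region") <- attr(system, "region")
  out
}
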