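#' Saturation scheme for a Z-spectrum acquisition
#'
#' Describes the RF saturation and recovery timing of one CEST acquisition:
#' a train of `n_pulses` rectangular pulses of `pulse_s` seconds separated by
#' `delay_s`, preceded by `recovery_s` of longitudinal recovery, swept over
#' `offsets_ppm`, with the normalization image acquired at `m0_offset_ppm`.
#' The default is the 1 s quasi-continuous scheme used throughout this
#' package: 10 x 100 ms pulses with 10 us gaps at B1 = 5 uT, 51 offsets from
#' -5 to +5 ppm in 0.2 ppm steps, M0 at -100 ppm, TR = 5 s (so 4 s recovery).
#'
#' The water Larmor frequency is stored explicitly so that the ppm-to-Hz
#' conversion is auditable; 499.9 MHz is the nominal proton frequency of an
#' "11.7 T" scanner.
#'
#' @param b1_ut Saturation amplitude (uT).
#' @param n_pulses Number of rectangular pulses.
#' @param pulse_s Single-pulse duration (s).
#' @param delay_s Inter-pulse delay (s).
#' @param recovery_s Pre-saturation T1 recovery time (s); use `Inf` for full
#'   thermal equilibrium.
#' @param b0_t Static field (T).
#' @param larmor_mhz Water resonance frequency (MHz).
#' @param offsets_ppm Ordered saturation offsets (ppm).
#' @param m0_offset_ppm Normalization offset (ppm).
#' @return An object of class `sat_scheme`.
#' @export
sat_scheme <- function(b1_ut = 5, n_pulses = 10, pulse_s = 0.1,
                       delay_s = 10e-6, recovery_s = 4, b0_t = 11.7,
                       larmor_mhz = 499.9,
                       offsets_ppm = seq(-5, 5, by = 0.2),
                       m0_offset_ppm = -100) {
  if (b1_ut < 0) abort("`b1_ut` must be >= 0.")
  if (any(c(n_pulses, pulse_s) <= 0) || delay_s < 0 || recovery_s < 0)
    abort("timing parameters must be non-negative (pulse count/duration > 0).")
  structure(
    list(
      b1_ut = b1_ut, n_pulses = as.integer(n_pulses), pulse_s = pulse_s,
      delay_s = delay_s, recovery_s = recovery_s, b0_t = b0_t,
      larmor_mhz = larmor_mhz, offsets_ppm = as.numeric(offsets_ppm),
      m0_offset_ppm = m0_offset_ppm
    ),
    class = "sat_scheme"
  )
}

#' @rdname sat_scheme
#' @param ... Fields to override in an existing scheme.
#' @param scheme A `sat_scheme` object.
#' @export
update_scheme <- function(scheme, ...) {
  stopifnot(inherits(scheme, "sat_scheme"))
  do.call(sat_scheme, modifyList(unclass(scheme), list(...)))
}

#' Low-power WASSR sweep scheme
#'
#' The water saturation shift referencing acquisition: B1 = 0.2 uT with
#' offsets from -1 to +1 ppm in 0.1 ppm steps, other timing as the parent
#' scheme.
#'
#' @param scheme The companion high-power [sat_scheme()].
#' @return A `sat_scheme` for the WASSR sweep.
#' @export
wassr_scheme <- function(scheme = sat_scheme()) {
  update_scheme(scheme, b1_ut = 0.2, offsets_ppm = seq(-1, 1, by = 0.1))
}

#' @export
print.sat_scheme <- function(x, ...) {
  tsat <- x$n_pulses * x$pulse_s + (x$n_pulses - 1) * x$delay_s
  cat("<sat_scheme>\n")
  cat(sprintf("  B1 = %g uT, %d x %g ms pulses (delay %g us), t_sat = %.4g s\n",
              x$b1_ut, x$n_pulses, x$pulse_s * 1e3, x$delay_s * 1e6, tsat))
  cat(sprintf("  recovery %g s, B0 = %g T (%g MHz)\n",
              x$recovery_s, x$b0_t, x$larmor_mhz))
  cat(sprintf("  %d offsets in [%g, %g] ppm, M0 at %g ppm\n",
              length(x$offsets_ppm), min(x$offsets_ppm), max(x$offsets_ppm),
              x$m0_offset_ppm))
  invisible(x)
}

#' Convert offsets between ppm and Hz for a scheme
#'
#' @param scheme A [sat_scheme()].
#' @param ppm,hz Values to convert.
#' @return Converted numeric vector.
#' @export
ppm_to_hz <- function(ppm, scheme) ppm * scheme$larmor_mhz

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, scheme) hz / scheme$larmor_mhz
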