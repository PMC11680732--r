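#' CSF contamination correction parameters
#'
#' Parameters of the partial-volume model used to remove the CSF
#' contribution from a Z-spectrum measured in a voxel that includes
#' ventricular CSF (typically the corpus callosum voxel, with an estimated
#' CSF volume fraction of 5-10%).
#'
#' @param f_csf CSF volume fraction in the voxel, in `[0, 1)`.
#' @param h2o_csf_M,h2o_tissue_M Water concentrations (M) of CSF and tissue.
#' @param t2_csf_s,t2_tissue_s Water T2 (s) of CSF and tissue.
#' @param te_s Echo time (s) of the readout.
#' @return A list of class `csf_params`.
#' @export
csf_params <- function(f_csf = 0.075, h2o_csf_M = 55.5, h2o_tissue_M = 40.0,
                       t2_csf_s = 110e-3, t2_tissue_s = 28.8e-3,
                       te_s = 25e-3) {
  if (f_csf < 0 || f_csf >= 1) abort("`f_csf` must be in [0, 1).")
  if (any(c(h2o_csf_M, h2o_tissue_M, t2_csf_s, t2_tissue_s) <= 0))
    abort("concentrations and T2 values must be > 0.")
  structure(list(f_csf = f_csf, h2o_csf_M = h2o_csf_M,
                 h2o_tissue_M = h2o_tissue_M, t2_csf_s = t2_csf_s,
                 t2_tissue_s = t2_tissue_s, te_s = te_s),
            class = "csf_params")
}

# magnetization ratio r = M0_CSF / M0_tissue at the echo time: volume and
# water-concentration ratio, weighted by the T2 decay of each compartment
# (long-T2 CSF decays less by TE, enhancing its relative contribution)
csf_m0_ratio <- function(params) {
  params$f_csf / (1 - params$f_csf) *
    params$h2o_csf_M / params$h2o_tissue_M *
    exp(-params$te_s / params$t2_csf_s) /
    exp(-params$te_s / params$t2_tissue_s)
}

#' Remove CSF contamination from a Z-spectrum
#'
#' Models the measured signal as a volume-weighted mix of a tissue spectrum
#' and a CSF spectrum, `M0_exp = M0_tissue (1 + r)` with
#' `r = M0_CSF/M0_tissue` from the partial-volume parameters, and inverts the
#' mix: `Z_corr = Z_exp (1 + r) - r Z_csf`. With `f_csf = 0`, or when the CSF
#' spectrum equals the measured one, the spectrum is returned unchanged.
#'
#' @param z_exp Measured Z-spectrum (tissue + CSF).
#' @param z_csf Reference CSF Z-spectrum (e.g. averaged over ventricles);
#'   interpolated onto the grid of `z_exp` if `interpolate = TRUE`.
#' @param params A [csf_params()] object.
#' @param interpolate Allow linear re-gridding of `z_csf` (default TRUE).
#' @return The corrected Z-spectrum on the grid of `z_exp`.
#' @export
csf_correct <- function(z_exp, z_csf, params = csf_params(),
                        interpolate = TRUE) {
  stopifnot(is_zspec(z_exp), is_zspec(z_csf))
  zc <- if (identical(z_csf$offset_ppm, z_exp$offset_ppm)) {
    z_csf$z
  } else if (interpolate) {
    approx(z_csf$offset_ppm, z_csf$z, xout = z_exp$offset_ppm, rule = 2)$y
  } else {
    abort("offset grids differ and `interpolate` is FALSE.")
  }
  r <- csf_m0_ratio(params)
  z <- z_exp$z * (1 + r) - zc * r
  z[!is.finite(z)] <- 0
  zspectrum(z_exp$offset_ppm, z,
            meta = c(zspec_meta(z_exp), list(csf_corrected = TRUE)))
}

#' Forward-mix a tissue and a CSF spectrum
#'
#' The forward model inverted by [csf_correct()]; useful for building
#' synthetic contaminated spectra. Exact inverse pair with [csf_correct()].
#'
#' @inheritParams csf_correct
#' @param z_tissue Pure tissue Z-spectrum.
#' @return The mixed spectrum on the grid of `z_tissue`.
#' @export
csf_mix <- function(z_tissue, z_csf, params = csf_params()) {
  stopifnot(is_zspec(z_tissue), is_zspec(z_csf))
  r <- csf_m0_ratio(params)
  zc <- approx(z_csf$offset_ppm, z_csf$z, xout = z_tissue$offset_ppm,
               rule = 2)$y
  zspectrum(z_tissue$offset_ppm, (z_tissue$z + r * zc) / (1 + r),
            meta = zspec_meta(z_tissue))
}

#' Estimate the B0 shift from a WASSR sweep
#'
#' Locates the direct-saturation minimum of a low-power (0.2 uT) water
#' saturation shift referencing spectrum by parabolic interpolation through
#' the discrete minimum and its two neighbours. A minimum at the sweep
#' boundary cannot be interpolated and is flagged as unreliable.
#'
#' @param low_power_zspec WASSR Z-spectrum covering about [-1, +1] ppm.
#' @return A one-row tibble with `shift_ppm` and `reliable`.
#' @export
wassr_b0_shift <- function(low_power_zspec) {
  stopifnot(is_zspec(low_power_zspec))
  x <- low_power_zspec$offset_ppm
  z <- low_power_zspec$z
  i <- which.min(z)
  if (i == 1L || i == length(z)) {
    warn("WASSR minimum at the sweep boundary: shift estimate unreliable.")
    return(tibble(shift_ppm = x[i], reliable = FALSE))
  }
  # vertex of the parabola through the discrete minimum and its neighbours
  d1 <- x[i] - x[i - 1]; d2 <- x[i] - x[i + 1]
  g1 <- z[i] - z[i - 1]; g2 <- z[i] - z[i + 1]
  denom <- d1 * g2 - d2 * g1
  shift <- if (abs(denom) > 0) {
    x[i] - 0.5 * (d1 * d1 * g2 - d2 * d2 * g1) / denom
  } else x[i]
  tibble(shift_ppm = shift, reliable = TRUE)
}

#' Re-center a Z-spectrum after a B0 shift
#'
#' Re-interpolates the spectrum onto its nominal offset grid after removing
#' the water-center displacement estimated by [wassr_b0_shift()]: the
#' spectrum value at nominal offset `x` is read off at `x + shift`. Natural
#' cubic spline interpolation; endpoints extrapolate flat.
#'
#' @param zspec The spectrum to correct.
#' @param shift A result of [wassr_b0_shift()], or a number (ppm).
#' @return The corrected spectrum on the original grid.
#' @export
apply_b0_shift <- function(zspec, shift) {
  stopifnot(is_zspec(zspec))
  s <- if (is.data.frame(shift)) shift$shift_ppm[1] else shift[1]
  span <- diff(range(zspec$offset_ppm))
  if (abs(s) > span) abort("shift larger than the sampled offset span.")
  if (s == 0) return(zspec)
  xq <- zspec$offset_ppm + s
  rng <- range(zspec$offset_ppm)
  xq <- pmin(pmax(xq, rng[1]), rng[2]) # flat extrapolation at the ends
  z <- spline(zspec$offset_ppm, zspec$z, xout = xq, method = "natural")$y
  zspectrum(zspec$offset_ppm, z,
            meta = c(zspec_meta(zspec), list(b0_shift_ppm = s)))
}

#' Rician noise-floor correction
#'
#' Magnitude images have a Rician noise floor that biases low signals upward;
#' near 0 ppm the water signal is fully saturated at 5 uT, so any residual
#' signal there estimates the floor. The floor `z0` is taken as the minimum
#' z within `+/-window_ppm` of 0 ppm and removed by rescaling,
#' `(z - z0) / (1 - z0)`, which maps 1 to 1 (preserving the M0
#' normalization).
#'
#' @param zspec The spectrum to correct.
#' @param window_ppm Half-width of the search window around 0 ppm.
#' @return The corrected spectrum.
#' @export
rician_floor_correct <- function(zspec, window_ppm = 0.2) {
  stopifnot(is_zspec(zspec))
  near <- abs(zspec$offset_ppm) <= window_ppm + 1e-9
  if (!any(near)) abort("no samples within the window around 0 ppm.")
  z0 <- min(zspec$z[near])
  if (z0 >= 1) abort("degenerate spectrum: floor estimate >= 1.")
  zspectrum(zspec$offset_ppm, (zspec$z - z0) / (1 - z0),
            meta = c(zspec_meta(zspec), list(rician_floor = z0)))
}
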