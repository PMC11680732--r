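---
title: "Quantitative glutamate CEST: model, calibration and simulation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative glutamate CEST: model, calibration and simulation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucest)
```

## The problem

Glutamate (Glu) is the main excitatory neurotransmitter; its amine protons
resonate about 3 ppm downfield of water and exchange with water protons at a
rate of order 10^3 s^-1. Chemical exchange saturation transfer (CEST) imaging
detects these dilute protons indirectly: a long off-resonance RF pulse
saturates them, exchange carries the saturation to water, and the water
signal drops. Sweeping the saturation offset gives the Z-spectrum
`z(offset) = Mz/M0`. The conventional glutamate-weighted contrast,
`MTR_asym(3 ppm) = z(-3) - z(+3)`, mixes the glutamate signal with
semisolid magnetization transfer (MT), amide and amine pools of
macromolecules, hydroxyl protons, and nuclear Overhauser effects (NOE), so
it is not quantitative. This package implements a quantitative alternative:
fit the whole Z-spectrum with a multi-pool Bloch-McConnell model, anchor the
glutamate exchange rate in vivo against MRS-measured concentrations, then
map glutamate concentration pixel by pixel with the exchange rate held at
its calibrated value.

## The forward model

Magnetization evolves under the Bloch-McConnell equations. Each Lorentzian
pool (water, Glu, Guan, APT, OH, NOE) carries transverse and longitudinal
components; exchange is star-shaped through water with back-rates fixed by
detailed balance (`k_water->i = f_i k_i`, so proton fractions and rates
stay thermodynamically consistent). The semisolid MT pool has a
microsecond T2: its transverse components are unresolvable at any feasible
offset grid, so it enters as a longitudinal-only compartment saturated at
the rate `pi * w1^2 * g(delta)`, with `g` the orientation-integrated
super-Lorentzian absorption lineshape. The orientation integral diverges on
resonance; inside a +/-1 ppm window the lineshape is replaced by the cubic
through flanking samples at +/-1 and +/-1.5 window widths (by symmetry an
even polynomial), the conventional way to avoid the unphysical infinity.
The lineshape quadrature is Gauss-Legendre, split at the magic angle where
the integrand peaks, and cached on a fine frequency grid inside the solver.

The reference acquisition is 10 x 100 ms rectangular pulses with 10 us
gaps (duty cycle 99.99%) at B1 = 5 uT, 51 offsets from -5 to +5 ppm in
0.2 ppm steps, normalization at -100 ppm, and a 4 s longitudinal recovery
before each offset (TR = 5 s minus 1 s saturation; recovery from zero
rather than full equilibrium matters because TR is only ~2.5 T1). Two
solvers are provided: the `analytic` solver treats the train as one
continuous block and evaluates the exact matrix solution
`M(t) = Mss + expm(A t)(M0 - Mss)`; the `numeric` solver propagates the
train pulse by pulse with piecewise-constant matrix exponentials. At the
default duty cycle they agree to better than 1e-4 in z, and the package
tests hold them to 1e-3 over random systems spanning the fitting bounds.
The Larmor frequency (499.9 MHz, the nominal proton frequency of an
"11.7 T" magnet) is stored in the scheme so every ppm-to-Hz conversion is
explicit.

The six-pool parameterization follows the in vivo literature for mouse
brain at 11.7 T: chemical shifts fixed (Glu +3.0, Guan +2.0, APT +3.5,
OH +1.0, NOE -3.5 ppm), non-Glu exchange rates fixed (300, 25, 2000,
15 Hz), metabolite T2 = 10 ms, MT T2 = 10 us, all T1 tied to the water T1.
Proton fractions convert to concentrations through
`[Glu] = f_H/3 * 2 [H2O]` (three amine protons per glutamate, two per
water), with `[H2O]` = 46.1 M in gray matter and 40.0 M in corpus
callosum.

## Preprocessing

* **CSF partial volume** (`csf_correct()`): a voxel containing a CSF
  fraction `f_csf` measures `M0_exp = M0_tissue (1 + r)` with
  `r = f_csf/(1-f_csf) * [H2O]_csf/[H2O]_tis * exp(-TE/T2_csf)/exp(-TE/T2_tis)`;
  the long CSF T2 weights its contribution up at the echo time. The
  corrected spectrum `Z = Z_exp (1+r) - r Z_csf` exactly inverts the
  forward mix (tested to 1e-6 and beyond).
* **B0 (WASSR)** (`wassr_b0_shift()`): the water-center displacement is
  the vertex of the parabola through the discrete minimum of a 0.2 uT
  sweep and its neighbours. This estimator is accurate to roughly
  0.01 ppm — and the quantification responds at about 2% [Glu] per
  0.001 ppm of mis-centering. The pipeline therefore removes the bulk
  shift by evaluating the *model* on the shifted axis (no data
  resampling, hence no interpolation error) and lets a free residual-shift
  parameter (`b0.shift_ppm`, bounds +/-0.05 ppm) absorb the estimator's
  error inside the fit. `apply_b0_shift()` (spline resampling of the data)
  is provided for workflows that need corrected spectra as data.
* **Rician floor** (`rician_floor_correct()`): magnitude images have a
  noise floor that biases low signals upward; at 5 uT water is fully
  saturated near 0 ppm, so the minimum z within +/-0.2 ppm estimates the
  floor, removed as `(z - z0)/(1 - z0)` (maps 1 to 1). The identical
  transform is applied to the model curve inside the fit residual —
  without this mirroring, the correction's rescaling biases every
  parameter. The rescale trades a small downward error in the unsaturated
  wings for floor removal where the signal is low; the package tests
  check the improvement in the saturated region where the floor matters.

## Fitting

`fit_zspectrum()` minimizes the residual sum of squares by bounded
Levenberg-Marquardt, in unit-scaled coordinates
(`(value-lower)/(upper-lower)`) so the finite-difference Jacobian is not
destroyed by the 7-decade spread between proton fractions (~1e-4) and
exchange rates (~1e3). Confidence half-widths are
`t_{0.975, n-k} * se` from the linearized covariance at the solution;
information criteria use the least-squares forms
`AIC = n log(rss/n) + 2k`, `cAIC = AIC + 2k(k+1)/(n-k-1)`,
`BIC = n log(rss/n) + k log n` with `k` the number of free parameters (no
variance term; only differences between models matter).

The residual landscape of the 10-11 parameter fit is genuinely multimodal:
the MT resonance offset, the water relaxation times and the MT
fraction-rate product trade against each other along flat curved valleys,
and plain descent from distant starting values routinely stalls a few
percent (in [Glu]) away from the optimum even on noiseless data. Three
layered remedies are built in, all deterministic under a fixed seed:

1. **Informed starts.** Quantification and calibration fits start at the
   calibrated regional model (the package's `striatum_system()` /
   `corpus_callosum_system()` values) rather than at the generic
   model-determination inits (MT offset -2.34 ppm, APT fraction 0.2%),
   which sit far from any plausible brain optimum. The glutamate exchange
   rate itself still starts at 8000 Hz with bounds 0-20000 Hz in the
   calibration fit.
2. **Structured multistart.** Extra starts place the water T1, MT exchange
   rate and MT fraction at physiologically low/high values (followed by
   seeded Latin-hypercube points), with early exit once a start's residual
   is consistent with the noise level
   (`rss < (n + 3 sqrt(2n)) sigma^2`).
3. **Basin hopping.** While the residual stays above that floor, up to 15
   seeded perturb-and-refit rounds (SD 0.08 in unit scale) around the
   incumbent escape the shallow valleys.

With all three, the noiseless recovery study concentrates at essentially
zero error (mean |error| ~0.2%, SD ~0.7% over 200 draws); with none of
them, errors of 5-15% are common. `select_model()` additionally
warm-starts every candidate from the best previously fitted candidate, so
that a nested model is never out-ranked merely because its own
optimization stalled.

## Calibration and mapping

`calibrate_kex_glu()` fixes each subject's glutamate fraction from its MRS
concentration and frees the exchange rate; per-subject estimates aggregate
into mean +/- SD. `quantify_glu()` inverts the roles: rate fixed at the
calibrated value (1301 Hz in gray matter), fraction free from 0 to the
equivalent of 40 mM. `fit_pixelwise()` applies the full preprocessing and
quantification per voxel of a 4-D stack, choosing the white-matter model
inside the corpus-callosum mask, and records per-voxel failures without
aborting. `mlsvd_denoise()` implements the multilinear-SVD truncation
(default core 30 x 30 spatial x 10 spectral) in the spatial-frequency
domain; acquired k-space is not available to the package, so the unitary
2-D DFT of the magnitude images stands in — a documented limitation, exact
only up to the phase information the magnitude operation has discarded.

## The simulation studies

`accuracy_precision_study()` draws tissue parameters uniformly from
realistic gray-matter ranges (water T1/T2 +/-10% of the regional values,
[Glu] 4-14 mM, Guan fraction 0.2-1%, OH 0-0.6%, NOE 2-6%, MT fraction
5-20%, MT rate 10-60 Hz, static-field offset +/-0.1 ppm; the amide
fraction stays at its mean fitted 3.5%), simulates the full acquisition
including the WASSR sweep, applies the measurement preprocessing, and
quantifies with the exchange rate fixed. Two range choices deserve note:
the OH range is capped at the fitting bound 0.6% so the generating truth
is always representable by the fitted model (a generator outside the model
class would force an irreducible bias, contradicting the intrinsic
accuracy the study measures); and every range brackets the mean in vivo
fitted values. The default 200 draws (a scaled-down stand-in for a
2000-draw study; the full size is one argument away) run in a few minutes.

`robustness_study()` sweeps one pool's generating exchange rate while the
fitting model keeps its assumed value. Noiselessly, the glutamate-rate
curve is minimized at the calibrated 1301 Hz and reaches about -11% at
800 Hz and -8% at 1850 Hz — the labeling-efficiency mismatch bias. Under
Rician noise the picture changes qualitatively: the Cramer-Rao bound for
[Glu] in the 11-parameter fit at sigma = 0.5% of M0 is ~66% of 6.5 mM
(21% even if every nuisance parameter were known exactly), so per-spectrum
noise, not rate mismatch, dominates any noisy robustness sweep. This is
the same noise sensitivity the in vivo workflow mitigates by tensor
denoising, and it is why the accuracy study's headline numbers are quoted
noiseless. At 2% noise the study reproduces the characteristic blow-up
(error SD above 100% and a positive bias from the concentration bound at
zero), consistent with published full-scale simulations of this design.

`make_phantom()` builds a small two-slice digital brain (gray-matter disc,
white-matter band, ventricle) with per-region or gradient glutamate truth,
full 51-offset stacks, M0 and WASSR companions, and seeded Rician noise.
It emulates the spectral physics exactly but not spatial point-spread,
coil profiles, motion, or B1 inhomogeneity — passing phantom tests
therefore validates the fitting chain, not the acquisition.

## Numerical choices and degenerate inputs

* Matrix exponentials by scaling-and-squaring; steady states by direct
  solve; the whole propagation is closed-form, no ODE stepping.
* A spectrum flat at 1 drives all CEST fractions to their zero bound and
  is flagged non-informative (excluded from calibration aggregates).
* A WASSR minimum on the sweep boundary is flagged unreliable and the
  shift is not applied.
* Fits report best-so-far with a warning when the iteration cap is hit;
  parameters within 1e-8 of a bound are flagged.
* `information_criteria()` requires `rss > 0`; a numerically perfect fit
  reports `-Inf` criteria rather than failing.
* All T1 values are tied to the water T1 during fitting (`tie_t1`),
  matching the model convention; untie for sensitivity analyses only.

## Known limitations

* The analytic/numeric solver pair shares the system assembly; it is
  validated against an independently hand-built implementation in the
  tests, not internally.
* The MLSVD denoiser operates on reconstructed magnitude images, not raw
  k-space.
* The exchange-rate calibration transfers only as far as the six-pool
  model does: pools missing from the model (e.g. a fast-exchanging
  vesicular glutamate compartment) bias the absolute concentrations while
  leaving contrasts largely intact.
* Quantifying the non-glutamate pools with this model is unreliable by
  design: their exchange rates are fixed assumptions, and the robustness
  sweeps show their estimated fractions respond strongly to those
  assumptions.

## A worked example

```{r example, eval = FALSE}
scheme <- sat_scheme()
z <- simulate_zspectrum(striatum_system(glu_mM = 6.5, kex_glu_hz = 1301),
                        scheme)

# calibrate the exchange rate against an MRS concentration
pairs <- tibble::tibble(zspec = list(z), glu_mM = 6.5, h2o_mM = 46100)
calibrate_kex_glu(pairs, striatum_system(), scheme)

# quantify an unknown spectrum with the calibrated rate
quantify_glu(z, kex_fixed_hz = 1301, h2o_mM = 46100, scheme = scheme)

# the noiseless accuracy study (scaled down)
accuracy_precision_study(study_config(n_draws = 50, noise_levels = 0,
                                      seed = 1))
```
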