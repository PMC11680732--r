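# glucest

Quantitative glutamate CEST (chemical exchange saturation transfer) imaging
for high-field brain MRI, in R.

Conventional glutamate-weighted CEST reports the asymmetry
`MTR_asym(3 ppm) = Z(-3) - Z(+3)` of the Z-spectrum (water signal
`Mz/M0` versus saturation offset). That contrast is not quantitative: at
B1 = 5 uT it mixes glutamate amine protons with semisolid magnetization
transfer (MT), guanidinium, amide, hydroxyl and NOE pools. `glucest`
implements the quantitative alternative:

1. **Forward model.** Multi-pool Bloch-McConnell simulation of the
   Z-spectrum under pulsed quasi-continuous saturation (10 x 100 ms
   rectangular pulses, 10 us gaps, B1 = 5 uT, 51 offsets in +/-5 ppm,
   M0 at -100 ppm, 11.7 T). Lorentzian pools carry full transverse +
   longitudinal dynamics with star-shaped exchange through water
   (detailed-balance back-rates `k_w->i = f_i k_i`); the MT pool is a
   longitudinal-only compartment saturated at `pi w1^2 g_SL(delta)` with a
   super-Lorentzian lineshape (interpolated +/-1 ppm around resonance).
   The propagator core is compiled (RcppArmadillo); an exact pulse-by-pulse
   solver cross-checks the continuous-wave solution.
2. **Preprocessing.** CSF partial-volume removal (exact inversion of the
   T2- and water-content-weighted mix), WASSR B0-shift estimation, and
   Rician noise-floor correction.
3. **Fitting and calibration.** Bounded least-squares Z-spectrum fitting
   with the six-pool brain model (water, MT, Glu, Guan, APT, OH, NOE),
   AIC/cAIC/BIC model selection, and calibration of the glutamate amine
   exchange rate against MRS concentrations:
   `[Glu] = f_H/3 * 2 [H2O]` links the fitted proton fraction to
   concentration. With the rate then fixed (1301 Hz in gray matter),
   per-spectrum and per-voxel glutamate concentrations are estimated.
4. **Mapping.** Pixel-wise quantification of 4-D CEST stacks (NIfTI IO,
   tissue-specific models via masks, multilinear-SVD denoising) into
   parametric maps with confidence and fit-quality companions.
5. **Simulation studies.** Accuracy/precision of the recovery under
   realistic parameter draws and Rician noise, exchange-rate robustness
   sweeps, and fully synthetic brain phantoms.

## Worked example

```r
library(glucest)

scheme <- sat_scheme()                   # the reference acquisition
sys <- striatum_system(glu_mM = 6.5, kex_glu_hz = 1301)
z <- simulate_zspectrum(sys, scheme)     # tibble: offset_ppm, z

mtr_asym(z, 3)
#> [1] 0.04530257

# calibrate the exchange rate against the MRS concentration
pairs <- tibble::tibble(zspec = list(z), glu_mM = 6.5, h2o_mM = 46100)
cal <- calibrate_kex_glu(pairs, striatum_system(), scheme)
cal$kex_mean_hz
#> [1] 1301

# quantify with the calibrated rate fixed
quantify_glu(z, kex_fixed_hz = 1301, h2o_mM = 46100, scheme = scheme)
#> # A tibble: 1 x 7
#>   glu_mM  ci95_mM      f_h    r2      rss converged reliable
#>    <dbl>    <dbl>    <dbl> <dbl>    <dbl> <lgl>     <lgl>
#> 1   6.50 1.02e-11 2.11e-4      1 1.26e-31 TRUE      TRUE
```

The asymmetry at 3 ppm is 4.5% of M0 (18% when normalized by `Mz(-3)`),
of which the glutamate pool itself contributes only a fraction — remove
the Glu pool and re-simulate to see the share. The calibration recovers
the generating exchange rate exactly on noiseless input, and the
quantification returns the generating 6.5 mM with a vanishing confidence
interval, confirming the pipeline is self-consistent.

A full study, scaled down:

```r
st <- accuracy_precision_study(study_config(n_draws = 40, noise_levels = 0,
                                            seed = 101))
st$summary
#> # A tibble: 1 x 5
#>   sigma     n mean_err_pct sd_err_pct mean_abs_err_pct
#>   <dbl> <int>        <dbl>      <dbl>            <dbl>
#> 1     0    40       -0.197      0.734            0.236
```

Each draw randomizes relaxation, pool fractions, MT parameters and the
static-field offset within realistic gray-matter ranges, simulates the
acquisition (including the WASSR sweep), preprocesses, and re-estimates
[Glu] with the exchange rate fixed: the model recovers concentration with
sub-percent intrinsic error.

A command-line front end for shell pipelines lives at `inst/cli/glucest`
(subcommands `simulate`, `correct`, `quantify`, `study`).

## Vignette

`vignettes/quantitative-glucest.Rmd` documents the model and its
assumptions, the preprocessing conventions, the optimizer design
(unit scaling, informed starts, structured multistart, basin hopping),
what the synthetic studies do and do not validate, and known limitations.
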