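---
title: "Estimating leaf nitrogen from canopy reflectance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf nitrogen from canopy reflectance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Leaf nitrogen concentration (leaf N, in % of dry mass) is the central
variable of crop N management, and wet-chemistry determination is slow and
destructive. Canopy reflectance in the visible/near-infrared range
(400-950 nm) responds to N status indirectly: chlorophyll absorption
deepens in the blue and red as N rises (so visible reflectance falls), the
red-edge transition near 700-730 nm shifts to longer wavelengths, and the
NIR plateau rises with canopy development. `nspec` implements the complete
chemometric workflow used to turn such spectra into a leaf-N calibration:

1. smooth the spectra (Savitzky-Golay, order 2, window 5);
2. transform them (none, first-derivative FDR, or continuum-removal CR);
3. calibrate four multivariate regressions (MLR, PCR, PLS, epsilon-SVR)
   with cross-validated order/hyperparameter selection;
4. evaluate by r², RMSE and RPD = SD/RMSE on a held-out split;
5. select effective wavelengths from the PLS fit by VIP scores and refit
   all methods on the reduced band set.

## The synthetic canopy generator

No field data ship with the package; every analysis is exercised against
`simulate_canopy_dataset()`, a mechanistic generator whose defaults define
the study conditions: 315 samples whose leaf N follows a truncated normal
with mean 3.80 %, SD 1.24 % and range 1.06-6.16 % (the underlying normal
is moment-matched so the *truncated* draw reproduces all four statistics),
split 165/150 into calibration and validation, on a 551-band 400-950 nm
grid with six informative wavelengths at 525, 573, 710, 780, 875 and
924 nm.

Each spectrum is a sum of:

* broad components — blue/red/green chlorophyll absorptions, a logistic
  red edge, an NIR plateau — whose N sensitivity is routed through a
  latent "structural N" `N + rnorm(structure_sd)`;
* narrow Gaussian features (SD 6 nm) at the informative centers, routed
  through a latent "expressed N" `N + rnorm(physiology_sd)`: absorption
  dips deepening with N in the visible, a growing red-edge bump at
  710 nm, and NIR dips that fill in as N rises;
* a per-sample smooth additive baseline (random orthogonal-polynomial
  series up to degree 8, coefficient scale `drift_amplitude`), emulating
  soil background and illumination changes;
* white per-scan noise of SD `noise_sd`, averaged over
  `scans_per_sample = 60` scans (implemented as dividing the SD by
  `sqrt(60)`, which is distributionally identical).

With all stochastic terms at zero the construction is deliberately
monotone: reflectance is non-increasing in leaf N at every visible band
(400-700 nm) and non-decreasing at every NIR band (750-950 nm), which
fixes the sign structure of the per-wavelength correlations.

### Why two latent N channels

The two scatter terms are what make the generator behave like field data
rather than like a noiseless forward model:

* `physiology_sd` (default 0.33 % N) is the scatter between leaf N and the
  pigment/protein pools that the narrow absorption features express.
  Because *every* spectral model reads N through these pools, it sets a
  common irreducible error floor — and it is the reason a refit on a
  handful of selected bands loses only a little RPD relative to the full
  spectrum, as observed in field studies. A chlorophyll-N coupling with
  r² around 0.85-0.9 is typical for wheat, which motivates the default.
* `structure_sd` (default 1.5 % N) is the looser coupling between N and
  the broad canopy-structure components (NIR level, absorption depths,
  red-edge position): LAI and biomass vary for many reasons other than N.
  Raw-reflectance models lean heavily on these broad channels and inherit
  their scatter; derivative spectra suppress them together with the
  additive baseline, which is how the FDR transform earns its advantage.

Without these channels (both zero) the spectra are a deterministic
function of N plus low-rank nuisance, and any multivariate regression is
essentially perfect — a regime that says nothing about real calibrations.

### What the generator does not emulate

No radiative transfer (no PROSAIL), no soil spectral libraries, no
multi-angle or illumination-geometry effects, no water-vapour features
beyond a fixed shallow 945 nm dip, no between-site or between-season
structure, and measurement noise is Gaussian and band-independent.
Passing tests therefore demonstrate that the *algorithms* behave as
specified under realistic statistical structure; they do not validate any
biological claim about wheat.

## Numerical choices

* **Savitzky-Golay edges.** The interior filter is the exact order-2,
  window-5 least-squares smoother (weights (-3, 12, 17, 12, -3)/35). At
  the edges the default policy mirror-pads the spectrum (`reflect`) so
  the grid length is preserved; `shrink` instead refits on the largest
  symmetric window that fits, copying the outermost bands unchanged.
* **FDR endpoints.** Interior bands use the central difference
  `(R[i+1] - R[i-1])/(2 * dl)`; the two endpoint bands use one-sided
  differences so the 551-band grid (and hence VIP indexing) is preserved.
* **Continuum removal.** One convex hull over the whole analysed range
  per sample (not per absorption feature), computed by a monotone-chain
  scan; collinear hull points are kept as vertices (their quotient is 1
  either way). The hull is anchored at both grid endpoints, where CR is
  exactly 1. Non-positive reflectance is rejected (the quotient would be
  undefined).
* **Cross-validation.** Leave-one-out is the default for PCR/PLS order
  selection; seeded k-fold (`cv_kfold()`) is available, and the SVR grid
  search defaults to 5-fold because leave-one-out across the 429-point
  default grid buys nothing but runtime. RMSECV ties resolve to the
  smallest order (parsimony).
* **Model preprocessing.** PCR and PLS mean-center the predictors but do
  not autoscale (all bands share reflectance units); SVR z-score
  standardizes the predictors and leaves the response in % N, so
  `epsilon` is in % N.
* **SVR gamma grid.** The RBF kernel is `exp(-g * ||u - v||^2)` on
  standardized predictors, so squared distances scale with the band
  count (about 2p). Useful kernel widths for 551-band spectra sit near
  g ~ 1/p, while reduced 6-12-band models favour g of order 1; the
  default half-decade grid therefore spans 1e-4 to 1e2 (and contains the
  classic reduced-band optimum c = 100, g = 3.16, epsilon = 0.1).
* **MLR with p >> n.** Full-spectrum MLR (551 bands, 165 samples) is fit
  as the minimum-norm least-squares solution via the SVD. Training
  residuals are then ~0 by construction; the method's weakness shows, as
  it should, on the validation split.
* **PLS details.** Single-response NIPALS with unit-norm weight vectors
  and X-deflation only (algebraically equivalent to deflating y as well
  for one response). VIP scores use the selected components only, with
  `SSY_a = q_a^2 t_a' t_a`; their squares average to exactly 1 over the
  bands, making 1.0 the natural threshold. The workflow's stricter
  threshold of 2.0 isolates only dominant bands.
* **Effective-wavelength distillation.** Contiguous runs of bands with
  VIP >= threshold each contribute their VIP-argmax band. Note that the
  *thresholded set* shrinks monotonically as the threshold rises, but the
  per-run picks can redistribute when a run splits.
* **Evaluation.** r² is the squared Pearson correlation of observed and
  predicted (not 1 - SSE/SST); RPD divides the observed split's SD (n-1
  denominator) by the RMSE; perfect prediction reports RPD = Inf. The
  performance bands are closed on both ends for "acceptable"
  (r² 0.50-0.75, RPD 1.40-2.00) and strict outside.
* **Region means.** UV 400-420, visible 420-700, NIR 700-950 nm, with
  boundary bands assigned to the lower-wavelength region.

## Open design points, resolved

* The best (transform, method) pair is chosen by highest validation RPD,
  breaking ties by validation r² and then by smaller model order. VIP is
  always computed from the *PLS* fit of the best transform, even when the
  best method is not PLS, because VIP is a PLS construct.
* The calibration/validation split is a seeded uniform random partition
  of samples; no stratification.
* The wavelength grid defaults to 400-950 nm at 1 nm (551 bands)
  throughout, matching the grid on which the multivariate analysis and
  the effective wavelengths are defined.
* A "coefficient of deviation" diagnostic sometimes quoted alongside
  slope and intercept has no recoverable definition; the evaluation
  report carries the predicted-vs-observed slope and intercept instead.

## Problem sizes and runtime

The packaged study runs at the full design size — 315 samples, 165/150
split, 551 bands, leave-one-out order selection for PCR/PLS (cap 20), and
the full 429-point SVR grid at 5-fold — in a few minutes on one CPU; the
test suite exercises the same conditions once and otherwise uses smaller
instances (10-50 bands, 20-70 samples) where an algebraic identity or an
oracle comparison is the point.

```{r study, eval = FALSE}
library(nspec)
cfg <- study_config(sim_config = simulation_config(seed = 42), seed = 42)
report <- run_study(cfg)
report
write_study_report(report, "report")
```

## Known limitations

* The generator's realism is statistical, not physical; transferring
  conclusions about method ranking to a particular sensor or crop still
  requires field data, which can be supplied as CSV via
  `study_config(data_csv = ...)`.
* Minimum-norm MLR is reported for completeness but is close to an
  interpolator at p >> n; its calibration-split metrics are not
  meaningful (validation metrics are).
* FDR's additive-baseline invariance is exact only up to floating-point
  rounding of `(x + c) - (y + c)`.
* `select_effective_wavelengths()` returns an empty frame (with a
  message) when nothing clears the threshold; downstream refitting is
  then skipped.
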