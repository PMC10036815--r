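---
title: "Chemometric workflows for wood density: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric workflows for wood density: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodnir)
```

# The problem and the data model

Vis-NIR reflectance spectra of wood cross-sections carry the overtone
and combination bands of hemicellulose, cellulose and lignin, and those
chemical components in turn covary with density. The package's data
model is a `spectra_dataset`: a samples × wavelengths matrix on a
strictly increasing 1 nm-type grid, per-row metadata (sample id,
species, location, replicate, density in g/cm³) and a mode flag for
reflectance versus absorbance. Replicate scans are averaged *in
reflectance* and the average is treated as the specimen's raw spectrum;
conversion to absorbance `A = log10(1/R)` happens afterwards. The order
matters — averaging and the log transform do not commute — and the
package fixes it this way deliberately, matching the convention that
the mean of repeated scans is the raw spectrum.

Model quality is summarized by four linked figures of merit:
`R² = 1 − SSres/SStot`, `RMSE = sqrt(SSres/n)`, `RPD = SD(y)/RMSE` and
`RSD = 100·RMSE/mean(y)`. RPD uses the *population* standard deviation
(denominator `n`), which makes the identity `RPD = (1 − R²)^(−1/2)`
exact whenever both are computed on the same data. This convention is
not arbitrary: published calibration tables in this field print
(R², RPD) pairs such as (0.812, 2.306), (0.823, 2.377) and
(0.901, 3.178) that reproduce to three decimals under the population
convention but not under the `n−1` convention at realistic sample
sizes. The test suite checks fourteen such pairs.

# Wavelet denoising and the lifting scheme

Denoising decomposes each spectrum to level `k`, thresholds every
detail band, and reconstructs. Two transforms are provided with one
shared boundary convention:

* `dwt_forward()` — the classical filter bank: periodic correlation
  with the analysis filters and dyadic downsampling.
* `lwt_forward()` — the lifting scheme: split into even/odd samples,
  then the wavelet's predict/update steps, then a diagonal scaling.

The lifting steps are obtained by factoring each wavelet's polyphase
matrix with the Euclidean algorithm on Laurent polynomials. Laurent
division is non-unique; the implementation chooses, at every division
step, between eliminating the highest or the lowest degree, picking the
variant with the smaller coefficient growth. Without this choice the
factorization of the longer symlets is numerically useless; with it,
lifting and filter-bank subbands agree to better than 1e-9 for all 18
registered wavelets (haar, db2–db8, sym2–sym8, bior1.1/1.3/1.5), and
round trips reconstruct to 1e-10. Haar uses the canonical two-step
factorization (predict `d = odd − even`, update `a = even + d/2`), so
the unnormalized transform returns pairwise differences and means.

Boundary handling composes an outer symmetric reflection pad (to a
multiple of `2^k`) with a periodic convention inside the transform;
perfect reconstruction is then exact by construction and the pad is
cropped after inversion.

The threshold is the per-level universal threshold
`λ_j = s·σ̂·sqrt(2 ln n_j)` with `σ̂ = median(|d₁|)/0.6745` estimated
from the finest level, soft thresholding by default, and a scale
multiplier `s` (default 1; `s = 0` is an exact no-op). All levels are
thresholded, not only the finest: the noise model is white, so every
detail band carries noise at a known level. These choices are standard
wavelet-denoising practice; the rule and scale are exposed in
`wavelet_spec()`.

`select_wavelet_params()` reproduces the sequential (greedy, not
exhaustive) search used in this field: stage 1 fixes order 3 and level
8 and compares haar, db3, sym3 and bior1.3 by cross-validated PLS
RMSECV on the denoised spectra; stage 2 scans the order within the
winning family (for the biorthogonal family the scan runs over the
registered bior1.Nd members, Nd ∈ {1, 3, 5}, since "order" is otherwise
ambiguous for a two-order family); stage 3 scans levels 1–8. RMSECV is
the primary criterion throughout; ties resolve to the earlier candidate
at a 1e-10 relative tolerance, so on data where denoising is inert the
first candidate wins deterministically.

# Scatter correction

MSC regresses each spectrum on a reference (`x ≈ a + b·ref`) and
returns `(x − a)/b`; the reference defaults to the calibration-set mean
and is stored so prediction spectra are corrected against the same
reference. SNV standardizes each spectrum to mean 0, sd 1 (`n−1`
denominator). A caveat the tests make explicit: MSC recovers the *clean*
spectra exactly only when the samples share one underlying spectrum and
the reference equals it; in general MSC maps every spectrum onto the
reference's scale. The generator round-trip test therefore uses
zero concentration spread and the known clean spectrum as reference.

# Wavelength selection

All four selectors consume a plain matrix and response and return a
`selection_result` (sorted 1-based indices, per-iteration history,
parameters, seed). Hyperparameter defaults follow the algorithms'
standard published settings, none being printed in the wood-density
literature this package mirrors: UVE noise scale 1e-10 and cutoff at
the 0.99 quantile of the artificial-variable reliabilities; CARS 50
Monte-Carlo runs, 80 % row sampling, 5-fold cross-validation; SPA scans
5–30 variables by default against a 25 % validation split; IRIV uses
500 binary-sampling rows (tests and the pipeline scale this down),
α = 0.05, and a greedy backward elimination. Ties in variable weights
resolve to the lower index. Within CARS, every candidate subset is
scored on the *same* cross-validation folds: with per-iteration random
folds the subset comparison is dominated by fold-assignment noise
rather than by the subsets themselves.

CARS's forced-retention schedule `r_i = a·e^{−ki}` is calibrated from
`r_1 = 1` and `r_N = 2/p`; the implementation snaps the endpoints
algebraically and applies a 1e-9-tolerant ceiling so the final forced
subset is exactly 2 variables regardless of floating-point error.

IRIV is quadratic-ish in the grid size; on full 2048-channel spectra the
pipeline therefore runs it on every 4th wavelength by default
(`iriv_downsample = 1` disables this).

# Calibration models and tuning

PLS1 is the NIPALS algorithm on column-centered data (centering only,
no autoscaling — the convention of the mainstream chemometrics
packages); PCR takes SVD components of the centered matrix. Both reduce
exactly to ordinary least squares at full rank, which the tests use as
the independent oracle. GRNN is Nadaraya–Watson kernel regression with
a Gaussian kernel — the GRNN network computes exactly this — with
exponent stabilization and a nearest-neighbour fallback on underflow.
SVR is ε-insensitive RBF regression via the libsvm solver in `e1071`,
with ε = 0.01 by default; when every target lies inside the ε-tube the
dual has no support vectors and the model degenerates to a constant
(taken as the midrange of the targets). Distance-based models (GRNN,
SVR) standardize predictors to unit variance using calibration-set
parameters; linear models only center. Centering/scaling parameters
are never recomputed on prediction data.

FOA follows the canonical two-dimensional formulation: flies perturb
the swarm axis, the candidate value is the reciprocal distance to the
origin (hence always positive — convenient for a spread parameter), and
the axis relocates to the best fly so far, making the best-score trace
non-increasing. Defaults: 20 flies, 100 iterations, axis initialized
uniformly in [0, 1], steps uniform in [−1, 1]. PSO uses
`v ← 0.8 v + 1.5 r₁ (pbest − x) + 1.7 r₂ (gbest − x)` with positions
clamped to the box, searching log₁₀(C) ∈ [−1.5, 3] and
log₁₀(g) ∈ [−3, 1.5] (i.e. C ∈ [2⁻⁵, 2¹⁰], g ∈ [2⁻¹⁰, 2⁵]).

The RSM layer tunes the three PSO meta-parameters — cross-validation
folds (5/10/15), maximum generations (50/75/100) and population
(20/40/60) — on a Box–Behnken design: the 12 edge midpoints plus 5
center replicates (17 runs, the common default of RSM software). A full
quadratic is fitted by least squares; significance is read from the
usual t statistics (a full ANOVA table adds nothing at 17 runs). The
minimum is located on a 41³ grid over the coded cube and snapped to the
nearest integer actual values, all three factors being counts. On a
bowl-shaped surface this returns the center point (10, 75, 40); on a
surface increasing in every coordinate it returns (5, 50, 20).

# The synthetic-data generator

The generator provides the statistical structure every method above is
designed to act on, with known ground truth:

* clean absorbance = Beer–Lambert mixture of Gaussian bands at 1157,
  1171, 1370, 1597, 1811, 1830, 2200 and 2353 nm (widths 20–45 nm),
  each loaded on one of three components; path length fixed at 1, as
  reflectance spectra define none;
* concentrations ~ normal truncated at zero (simple, positive,
  seedable), defaults mean ≈ 0.3, sd 0.08;
* density = 0.45 + 0.50·c₁ + 0.45·c₂ + 0.50·c₃ (+ an optional
  quadratic term), giving densities within 0.50–1.20 g/cm³ — bracketing
  the 0.576–1.124 g/cm³ range reported for the temperate species this
  package targets;
* per-sample affine scatter (slope 0.95–1.05, offset ±0.02) and a
  degree-2 polynomial baseline (amplitude 0.02) — exactly what MSC/SNV
  remove; white noise of sd 0.005 per replicate (replicates share
  everything else); three replicates per specimen;
* reflectance `10^(−A)` clipped to [1e-6, 1] so `log10(1/R)` always
  exists.

What it does **not** emulate: quantitative wood chemistry, instrument
line shape, water-vapor bands, wavelength-dependent noise, or
between-tree covariance structure. Consequently, passing recovery tests
show the algorithms behave correctly *under their own assumptions*, not
that they will attain any particular accuracy on measured wood spectra.

Three testing regimes deserve explanation:

* **Band recovery** (CARS/IRIV select ≥ 80 % of wavelengths inside the
  planted ±2·width windows; n = 120, p = 256, noise 0.005, five seeds).
  Scatter and baseline are disabled here: with them on, off-band
  wavelengths genuinely reduce RMSECV by cancelling the baseline, so
  "selected outside the bands" is not an error of the selector. CARS
  weights use 3 latent variables — the rank of the three-component
  signal; with a heavily overparameterized coefficient vector the
  weighted resampling keeps diffuse noise columns on near-noiseless
  data. The Gaussian tails also mean the stored ±2σ window slightly
  undercounts true signal; the signal-locality test uses ±8σ, where the
  tail is below 1e-12.
* **Denoising benefit** (searched LWT denoising lowers PLS RMSECV).
  The gain depends on the decomposition level, which is precisely what
  the sequential search chooses — so the test runs the search first and
  compares its best candidate with the raw spectra under an identical
  cross-validation protocol. At the minimum noise level (sd 0.01) the
  gain is a few percent and occasionally vanishes on a lucky noise
  draw; the acceptance script averages the gain over five seeds at
  sd 0.02, squarely inside the noisy regime the denoiser targets.
* **Nonlinear stress configuration** (tuned GRNN/SVR beat PLS in ≥ 4/5
  seeds). The default quadratic term is locally near-linear over the
  concentration range, and no kernel method can beat a well-specified
  linear model there. The stress configuration places the density
  parabola's vertex inside the concentration range
  (`density_slopes = −5.7`, `nonlinearity_strength = 3`,
  `density_intercept = 3.6`), removing most of the linear component.
  Models are compared on a CARS-selected subset, as the full workflow
  does. Densities in this configuration exceed the wood range — it is a
  stress test of model class, not a realistic wood scenario.

# Pipeline and problem sizes

`run_single_species()` chains, per species: replicate averaging →
absorbance → stratified 70/30 split (floor rule per species, at least
one prediction sample; the split warns if a prediction density falls
outside the calibration range) → wavelet-parameter search → LWT
denoising → selector comparison against full-spectrum and
denoised-spectrum PLS baselines → the configured models on the subset
with the best selector RMSECV → prediction metrics for both raw and
denoised prediction spectra. The winning selector is chosen by RMSECV
rather than by hand, so the comparison table and the model table stay
consistent without a human in the loop. A failing species branch is
reported and skipped. `run_combined()` contrasts per-group "signal"
models with pooled "combined" PLS/PCR models across species and
locations.

Default test and example sizes are 24–120 samples on a 256-point grid
(350–2390 nm at 8 nm), with the full 2048-point grid exercised where
the property under test depends on it (transform round trips, denoising
gain, grid counts). The `light = TRUE` preset of `run_config()` shrinks
the optimizer budgets and drops the RSM-PSO-SVR sweep, whose 17 design
runs of swarm-tuned SVR cross-validation dominate the cost of
everything else combined; the composed trainer retains its own
scaled-down test and remains available in the full configuration.

# Known limitations

* The lifting factorization is computed numerically; exotic filters
  outside the registered set are not accepted, by design.
* IRIV's cost grows quickly with the grid; the default downsampling
  trades resolution for tractability on 2048-channel spectra.
* GRNN cannot extrapolate beyond the calibration target range; with
  random splitting the prediction set occasionally extends past the
  calibration range (the split warns when it does).
* The RSM layer fits a quadratic in the coded cube; if the true CVmse
  surface has structure sharper than quadratic between the three coded
  levels, the snapped optimum can miss it — an inherent limit of a
  17-run design.
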