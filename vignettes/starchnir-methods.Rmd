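---
title: "Methods: chemometric calibration of fresh-root starch from short-wave NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric calibration of fresh-root starch from short-wave NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starchnir)
```

## The problem

Cassava breeding programs select for fresh-root starch content, a trait
whose wet-lab reference measurement (wet-milling extraction, settling,
drying, weighing) takes days per batch. Pocket-sized short-wave NIR
sensors covering 740–1070 nm at 1 nm resolution offer a fast proxy: the
third C–H overtone of carbohydrates and the second O–H overtone of water
both fall in the 815–980 nm window, so reflectance spectra of shredded
root tissue carry a starch signal. `starchnir` implements the complete
calibration workflow for this setting: spectral pretreatment, outlier
screening, multivariate calibration with genotype-grouped validation,
wavelength importance, and quantitative-genetic analysis of both the
trait and the spectra themselves.

Because no public plot-level dataset of this kind exists, the package
ships a first-class synthetic generator. Every claim the test suite makes
is a claim about recovery of known ground truth from that generator, not
about any particular field experiment.

## The synthetic world

`sim_config()` describes a set of field trials and a spectral forward
model.

**Phenotypes.** Plot values are drawn from exactly the mixed models the
heritability module later fits: for a randomized complete block design
(RCBD) `Y = mu + G_i + b_j + e`, and for an alpha-lattice
`Y = mu + G_i + Rep_j + b_k(j) + e`, all effects independent normal. The
defaults (`starch_mean = 25`, `var_g = 36`, `var_rep = 1`,
`var_block = 1`, `var_e = 6`, 150 genotypes, 2 replicates) give plot
values with a coefficient of variation near 0.27 and entry-mean
heritability near 0.9 — the profile of a high-variability preliminary
yield trial, the setting in which NIRS calibration works best and which
published trait tables (starch 4–42 %, trial CVs 0.1–0.37) identify as
the relevant envelope. A configurable fraction of genotypes (default
0.25) is shared across trials with identical genetic effects, which is
what makes the tested/untested-genotype validation schemes meaningful.

**Spectra.** Each plot's noise-free spectrum is a flat baseline (0.40
reflectance) plus Gaussian absorption bands at 880, 912, 960 and 975 nm
whose amplitudes are linear in starch, plus a water band at 970 nm whose
amplitude *decreases* with starch (`0.05 - 0.0008 * starch`): wetter
tissue means less starch, so the water signal is negatively informative.
Band centres follow the wavelengths that variable-importance analysis of
real data flags as informative. Each of the 3 technical scans per plot
then receives multiplicative scatter `(1 + slope)`, an additive offset,
and white noise — exactly the distortions SNV and derivative
pretreatments exist to remove, so pretreatment efficacy is testable.
Scan-to-scan noise within a plot is not reported in the literature for
this protocol; the default is 10 % of the per-sample noise SD
(`scan_noise_sd`), configurable.

What the generator does **not** emulate: wavelength-correlated
(pink/structured) instrument noise, nonlinear detector response,
temperature drift, and the proprietary cloud-side smoothing of
commercial pocket sensors. A green end-to-end test therefore establishes
that the pipeline's statistics and bookkeeping are correct, not that any
physical instrument will achieve the simulated accuracy.

One consequence of the white-noise choice is worth stating: bare
finite-difference derivatives (D1, D2, and SNV followed by either)
amplify white noise at 1 nm spacing and visibly degrade cross-validated
accuracy in this world (R²cv drops from ≈0.99 raw to ≈0.5 for SNV1D),
while window-11 Savitzky–Golay variants do not. This mirrors the
real-world rationale for smoothing derivatives and is left as a feature
of the stated world, not tuned away.

## Pretreatment

Thirteen named variants (raw plus twelve combinations) are exposed as
pure operators through `apply_pretreatment()`:

* **SNV** centres and scales each spectrum to mean 0, sample SD 1.
  Zero-variance spectra cannot be scaled and are dropped with a warning.
* **Savitzky–Golay** fits a local least-squares polynomial in a centred
  odd window and evaluates its `d`-th derivative. Polynomial order
  defaults to 2 for smoothing/first derivatives and 3 for second
  derivatives (the underlying wrapper packages do not state theirs; both
  are configurable). The bare `SG` and `SNVSG` variants use window 11.
* **Gap-segment derivatives** difference two averaged flank segments
  separated by a gap, normalised by the centre-to-centre flank distance.
  The named `SGD1` variant has window 11; the split within that window is
  not stated anywhere, so the package defaults to segment 3 / gap 5 and
  exposes both. Standalone D1/D2 are the degenerate case
  segment = 1, gap = 1 (plain central differences), matching common
  chemometrics-package behaviour.
* **Edge handling:** edge points with incomplete windows are dropped, not
  padded — no extrapolated values ever enter a model, at the cost of a
  slightly narrower grid (reported on the returned object).

Scatter correction always precedes smoothing/differentiation in composed
variants.

## Outlier screening

Exploratory PCA (`pca_spectra()`) is column-mean-centred SVD. The
Mahalanobis filter works in PCA score space because with 331 wavelengths
and at most a few hundred samples the raw covariance is singular. Scores
retaining 95 % cumulative variance (capped at n − 2 components) are
standardised per component and the distance reported as
`sqrt(mean(z^2))`, so the conventional threshold of 3 behaves like a
3-SD rule whatever the component count. The 95 % cap is a deliberate
design choice: under white spectral noise a 99 % rule drags in dozens of
pure-noise components, and dividing by `sqrt(k)` then dilutes a genuine
single-direction outlier below any useful threshold (a planted 10-SD
outlier lands at distance ≈1.7 under 99 % retention versus ≈5 under
95 %). Visual PCA-based removal of aberrant genotypes, which human
analysts do before the numeric rule, is intentionally not automated.

## Calibration models

**PLSR** is implemented from scratch (univariate-response NIPALS with
mean centring) because rank selection, loadings and VIP importance all
need its internals. The regression vector is stored for *every* rank up
to the cap, so cross-validation over ranks costs one fit per fold. At
full rank PLSR reproduces ordinary least squares, which the test suite
uses as an oracle; training RMSE is non-increasing in rank and score
vectors are mutually orthogonal by construction.

**SVM (radial kernel)** is a least-squares SVM: kernel ridge regression
with an intercept, solved in closed form. The environment this package
targets has no libsvm-style binding, and the least-squares formulation
keeps the radial-kernel geometry while remaining dependency-free and
deterministic. **Random forest** is a first-party bagged regression-tree
ensemble (bootstrap rows, `mtry` random candidate features per split,
exhaustive cumsum-based variance-reduction split search). Both honour
the same fit/predict contract as PLSR so evaluation code is
algorithm-agnostic.

**Tuning** (`select_hyperparameters()`) is plain minimum-RMSECV over a
5-fold partition, grouped by genotype whenever labels are available so
replicate plots never straddle folds. The PLSR rank cap defaults to 10,
sized for trials of a few dozen to a few hundred plots. No one-SE rule is
applied: the selection criterion is "the model with the best prediction
ability", i.e. the minimum. The SVM gamma grid is multiples
(0.25, 1, 4) of the `1/(p * mean variance)` heuristic with costs
(1, 10, 100); whether real analyses tuned gamma or used a heuristic
default is unstated, so the grid is documented configuration, not dogma.

## Validation

`within_trial_evaluate()` repeats, 50 times by default: draw a
genotype-grouped 70/30 split (fraction applied to genotype counts,
floor to training), tune on the training side, fit, score the held-out
side. `build_cv_scheme()` adds the four breeder-relevant scenarios:

| scheme | test set | training set |
|---|---|---|
| CV2 | round(0.3 · G) of the focal trial's genotypes, focal-trial plots | everything else, including other-trial plots of test genotypes |
| CV1 | same draws as CV2 under the same seed | CV2 training minus *all* plots of test genotypes |
| CV0 | the entire focal trial | all other trials |
| CV00 | the entire focal trial | all other trials minus any genotype occurring in the focal trial |

CV1/CV2 are resampled (50 iterations); CV0/CV00 are deterministic single
plans. A property test verifies the set relations of every emitted plan
over 100 seeds. Note the two stated sizing rules differ by design:
grouped splits floor the *training* count, the CV2 builder rounds the
*test* count; they coincide at 10 genotypes and differ at, e.g., 18.

**Metrics** (`compute_metrics()`): R²p is the squared Pearson correlation
(reported in [0, 1] even for anti-correlated predictions), RMSEP the
root-mean-square test error, bias the mean signed error, SEP the
bias-corrected sample SD of residuals, RPD = SD(obs)/RMSEP and
RPIQ = IQR(obs)/RMSEP — both deliberately sharing RMSEP as denominator
(so RPIQ/RPD = IQR/SD exactly; the literature lists SEP and RPD side by
side without fixing the base, and RMSEP is the wrapper-package
convention), with type-7 quantiles for the IQR. Lin's CCC uses
n-denominator moments, which guarantees CCC ≤ |r| with equality only at
perfect scale and location match. Perfect predictions make RPD/RPIQ
undefined; they are reported as `NA`.

## Importance and heritability

No importance formula is fixed by the protocol this package follows, so
the de-facto standards are used and documented as interpretive choices:
**VIP** for PLSR (mean squared score exactly 1 over wavelengths; scores
computed on the pretreated wavelength axis and mapped back to nm) and
**permutation importance** (mean RMSE increase over seeded column
shuffles) for the other models, impurity-based alternatives being
deliberately out of scope. Ties in top-k reporting break toward the
shorter wavelength.

Variance components come from REML fits of the two field-design models —
`(1|genotype) + (1|block)` for RCBD,
`(1|genotype) + (1|rep) + (1|rep:block)` for alpha-lattices — via lme4
(the standard engine for such models in plant breeding), with the bobyqa
optimizer tightened (`rhoend = 1e-13`) so balanced-design estimates agree
with the ANOVA closed form to the 1e-6 the oracle tests demand. The
printed alpha-lattice model in the source protocol reuses one variance
symbol for replicates and blocks — treated here as a typo; a distinct
replicate component is estimated. Broad-sense heritability is the
entry-mean formula `H2 = 100 * vg / (vg + ve / nRep)` with `nRep` the
arithmetic mean plot count per genotype (computed on the 0–100 scale;
the 0–1 convention seen in plots is the same number divided by 100).
`spectral_heritability_scan()` applies the appropriate model
independently at each wavelength, recording per-wavelength convergence
and continuing past failures.

## Numerical and degenerate-input policy

* Fixed seeds make every stage bit-reproducible; the pipeline derives
  per-iteration seeds from a single top-level seed.
* Zero-variance responses are a fit error; zero-variance spectra are
  excluded from SNV with a warning; all-constant trait vectors short-cut
  to all-zero variance components.
* Variance estimates are non-negative by construction (REML boundary);
  H2 is `NA` when every component is zero.
* Fewer than 3 samples skips QC with a warning rather than failing.

## Known limitations

* The forward model is linear in starch with Gaussian bands — adequate
  for validating the statistics, not a radiative-transfer model.
* The least-squares SVM differs from epsilon-insensitive SVR in its loss;
  with the small, dense designs used here the practical difference is
  shrinkage behaviour, not accuracy ranking.
* The pure-R random forest is sized for hundreds of samples and a few
  hundred wavelengths; it is the slowest of the three algorithms.
* CV0/CV00 return a single plan per focal trial, so no dispersion is
  attached to their metrics (matching how such schemes are reported).
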