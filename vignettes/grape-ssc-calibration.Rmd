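---
title: "Calibrating grape soluble solids content from 18-band Vis/NIR spectra"
author: "grapeSpec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating grape soluble solids content from 18-band Vis/NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapeSpec)
```

## The problem

Soluble solids content (SSC, measured refractometrically in °Brix) is the
working ripeness indicator for wine grapes: one degree Brix corresponds to
roughly 10 g/L of sugar. Diffuse Vis/NIR reflectance carries SSC
information — pigment absorption in the visible range and C–H/O–H overtone
absorption in the NIR — so a cheap 18-channel filter photometer
(410–940 nm centers, 20 nm FWHM) can in principle predict SSC
non-destructively. In practice the raw channel data are degraded by
multiplicative scatter, baseline drift, channel noise, occasional corrupted
acquisitions, and reference-measurement errors. This package implements the
data-optimization chain that deals with each of those in turn: outlier
screening, spectral preprocessing, characteristic-wavelength selection,
representative calibration/validation partitioning, and partial least
squares (PLS) calibration.

The central container is `SpectraSet`, an S4 class extending
`SummarizedExperiment`: bands are rows (`rowData` holds the band schema,
center wavelength and FWHM in nm), samples are columns (`colData` holds the
SSC reference in °Brix and optional acquisition timestamps), and the single
assay stores dimensionless reflectance. Calibrated reflectance is
deliberately not clipped to [0, 1]: values slightly above 1 occur on glossy
berries and are informative for outlier screening.

## The synthetic study conditions

Because field campaigns are expensive and rarely shareable, the package
ships a statistical generator whose defaults define the study conditions
used throughout the tests:

* **SSC**: truncated normal, mean 22.03 °Brix, sd 0.86 °Brix, range
  20.00–24.60 °Brix — a harvest-ripe red-grape batch of `nSamples = 120`
  (one day's sampling).
* **Clean spectrum**: a smooth base shape with the qualitative features of
  red-grape reflectance — an anthocyanin absorption dip near 500 nm, a
  chlorophyll dip near 680 nm with the reflectance trough around 705 nm,
  and a monotone rise through the NIR overtone region (760–940 nm).
* **Signal**: reflectance responds to SSC linearly at a small set of
  informative bands (default 410, 610 and 900 nm) with `effectSize = 0.02`
  reflectance per °Brix — about 2% of mid-scale signal per degree, a
  realistic pigment/absorption-linked response for a low-cost sensor.
* **Degradations**: per-sample multiplicative scatter
  ((1 + slope)·x + offset, slope sd 0.05, offset sd 0.02) — exactly the
  structure MSC and SNV are designed to remove — plus additive channel
  noise (sd 0.01 reflectance, typical of a low-cost filter photometer).
* **Planted anomalies**: `injectOutliers()` corrupts chosen samples with
  inflated channel noise (spectral outliers), shifted SSC references
  (chemical outliers), or both, returning the ground-truth ids so detector
  recovery is measurable.

What the generator does *not* emulate: real instruments drift over time,
real absorption features are spectrally broad rather than confined to
single channels, temperature affects both the optics and the juice, and
berry-to-berry heterogeneity is not i.i.d. Passing tests on this generator
therefore demonstrate algorithmic correctness and calibrated error rates
under the stated statistical structure, not field performance. One
consequence of the single-channel signal convention deserves emphasis: a
delta-like signal is high-frequency along the wavelength axis, so channel
smoothing attenuates it at least as much as it attenuates white noise, and
smoothing does not improve validation accuracy on these synthetic data even
though it typically does on real spectra, where the chemical signal is
broad. The package's end-to-end pattern check computes and documents
exactly this behavior.

```{r generator, eval = FALSE}
x <- generateDataset(generatorConfig(nSamples = 120, seed = 1))
inj <- injectOutliers(x, kind = "both", n = 3, magnitude = 8, seed = 2)
```

## Outlier screening

Two complementary screens run on the raw spectra, before preprocessing.

**Monte-Carlo residual screening** (`mcOutlierDetect`) repeatedly draws a
random calibration subset (default 80% of samples, 1000 iterations), fits a
PLS model, and predicts the held-out remainder. Each sample accumulates
signed prediction residuals (predicted − reference). A sample whose
residual *mean* is unusually large in magnitude disagrees systematically
with the population model — a chemical (reference-value) outlier; one whose
residual *sd* is unusually large predicts erratically — a spectral outlier;
both together mark a doubly corrupted sample (`quadrantClassify`).
Thresholds are `mean(stat) + k·sd(stat)` with `k = 2.5` by default, applied
to |residual mean| and to residual sd. Flagging on the magnitude rather
than the signed mean is deliberate: a corrupted refractometer reading can
err in either direction, and a one-sided rule would miss half of them. The
signed means are still reported for the quadrant plot. Two numerical
choices matter: per-sample statistics below 10⁻⁸ °Brix are clamped to zero
so that perfectly linear noise-free data produce no flags under the
relative k·σ rule, and subset draws are keyed to id-sorted order so the
flag set is invariant to row order. The number of latent variables is
chosen once on the full set by cross-validation unless given.

**PCA/Hotelling screening** (`pcaHotellingDetect`) decomposes the
column-centered spectra and computes each sample's Hotelling statistic over
the first k = 2 components, T²ᵢ = Σ t²ᵢₖ/λₖ, against the small-sample
F-based limit [k(n−1)(n+1)/(n(n−k))]·F₁₋α(k, n−k) at α = 0.05 — the 95%
confidence ellipse in score space. The F form is used rather than the χ²
asymptote because n is in the low hundreds. A zero eigenvalue among the
first k components is an error, not a silent skip.

`combineOutliers` merges the two flag sets. The default is the **union**:
the two screens respond to different corruption mechanisms, so a sample
flagged by either is suspect; the intersection (samples flagged by both) is
selectable for conservative removal.

## The eight preprocessing methods

All methods are `SpectraSet → PreprocessResult`; fitted state, where it
exists, is stored so validation data can be transformed with calibration
parameters only (`applyPreprocess`).

* **FD/SD** (baseline correction): divided differences over the
  *wavelength* grid, FDᵢ = (xᵢ₊₁ − xᵢ)/(λᵢ₊₁ − λᵢ), assigned to midpoint
  wavelengths. The channel spacing varies from 25 to 50 nm, so raw index
  differences would conflate spacing with slope; the divided-difference
  convention is documented package behavior, not a claim about any
  particular instrument's software. The band axis shrinks by one per
  order and downstream stages consume the midpoint schema.
* **MSC/SNV** (scatter correction): MSC regresses each spectrum on a
  reference (default: the column-mean spectrum, stored for new data) and
  returns (row − a)/b; a row with zero slope against the reference is
  flagged, warned about, and returned unchanged rather than divided by
  ~0. SNV standardizes each row to mean 0, sd 1 (n−1 denominator). On
  generator data with scatter and no noise both collapse between-sample
  variance to numerical zero by construction.
* **MAS/SGS** (smoothing): MAS is a centered moving mean (default window 3)
  with reflection-padded edges. SGS is Savitzky–Golay local polynomial
  smoothing (default window 5, order 2 — the smallest sensible smoother
  for an 18-point spectrum); its edges use the standard polynomial-fit
  edge treatment, which preserves the defining exactness property
  (polynomial trends of degree ≤ order pass through unchanged) over the
  whole axis, where reflection padding would break it at the edges.
* **Normalization/autoscaling** (scaling): min-max normalization is
  per-spectrum (each row spans exactly [0, 1]); autoscaling is
  per-variable (each band to mean 0, sd 1 across samples, with the column
  statistics stored for new data). The row/column distinction is what
  makes the two methods behave differently downstream.

## Wavelength selection

**UVE** (`uveSelect`) appends `noiseCount = 18` uniform-random columns
scaled to 10⁻¹⁰ of the smallest real-column sd, fits one PLS model per
leave-one-out fold, and computes each variable's stability = mean/sd of its
regression coefficient across folds. Real variables whose |stability|
exceeds the maximal |noise stability| (cutoff multiplier 1) are kept. A
coefficient with zero sd across folds gets signed-infinite stability (zero
if its mean is also zero). Noise columns are excluded from the selection by
construction. Note the specificity limit inherent in this cutoff rule: with
as many noise as real variables, a pure-noise response still leaves roughly
a coin-flip chance that some real variable exceeds the noise maximum, so an
empty selection under the null is *not* guaranteed; raising `noiseCount` or
`cutoffMultiplier` trades sensitivity for specificity.

**SPA** (`spaSelect`) grows a candidate chain from every start variable by
repeatedly adding the column with the largest projection norm onto the
orthogonal complement of the span of the chosen columns (columns autoscaled
first); every (start, length) prefix is scored by OLS RMSE on an SPXY
held-out validation fraction (default 25%), and the global minimizer wins.
Ties break toward the shorter chain, then the lower start index. The whole
procedure is deterministic — there is no seed to set. Degenerate collinear
input truncates chains early; shorter prefixes are still scored. Because
chain growth is response-blind (only the start and the prefix scoring see
y), SPA explores a small fraction of all subsets and is not expected to
match an exhaustive subset search; it trades optimality for speed and
collinearity control.

Variable indices are 1-based into the band schema; every output also
carries wavelengths in nm, which are the unambiguous identifiers.

## Partitioning, regression, and metrics

**SPXY** (`spxySplit`) computes normalized joint distances
d = dx/max(dx) + dy/max(dy) (Euclidean on spectra, absolute on SSC), seeds
the calibration set with the two mutually farthest samples, and repeatedly
adds the sample whose minimum distance to the current calibration set is
maximal, until `round(calFraction · n)` samples (default 75%) are reached.
An explicit `calSize` override allows splits like 83/30 on 113 samples that
a rounded fraction cannot express. Ties break toward the lower sample id,
making the split row-order invariant. A constant response degrades to
Kennard–Stone on X with a warning.

**PLS** (`plsFit`) is PLS1 by NIPALS with column-mean centering and no
scaling — scaling is a preprocessing decision, which keeps the eight
methods comparable. Requested components beyond the effective rank are
truncated with a warning. The composed coefficient vector reproduces the
latent-score prediction path to numerical precision, and with full
components the solution equals ordinary least squares; both identities are
tested, and predictions are cross-checked against an independent PLS
implementation.

**Latent-variable choice** (`chooseNLatent`) cross-validates RMSE (default
leave-one-out; fold assignment seeded and keyed by sample id) over
1..maxLatent and picks the smallest count within 2% of the minimum — a
parsimony rule that avoids chasing CV noise into extra components.

**Metrics** (`evaluateFit`): RC²/RV² are coefficients of determination
1 − SSres/SStot with SStot about each set's own mean (not squared Pearson
correlations — the two differ for biased predictions), and RMSEC/RMSEV are
root-mean-square errors in °Brix.

## Pipeline ordering and leakage

`runPipeline` follows the conventional chemometric ordering: outlier
screening on the raw full set, then preprocessing, then wavelength
selection, then the SPXY split, then PLS. Selection before splitting leaks
information by modern standards; it is kept as the default for fidelity to
common practice, and `strictNesting = TRUE` reorders the run so that the
split comes first and preprocessing state and selection are computed on
calibration rows only (validation rows are transformed with stored
calibration parameters). With strict nesting, perturbing a validation
sample cannot change any fitted state — a property the tests assert.

Each run archives its configuration (YAML), per-cell fit reports, the
outlier report (CSV + JSON), and a log; identical configurations produce
byte-identical outputs.

## Problem sizes used by the tests

The test suite and the acceptance script run at desk scale, chosen as the
package's own trade-off between statistical resolution and turnaround:
batches of 40–120 synthetic samples; 150–500 Monte-Carlo iterations;
recovery and calibration rates over 50–100 seeded repetitions; the
end-to-end pattern over 20 generator seeds at the full n = 120 study
conditions. All stochastic stages are seeded, so every reported number is
reproducible.

## Known limitations

* The generator is statistical, not a radiative-transfer model of grape
  tissue; absolute reflectance levels are conventional.
* The single-channel SSC signal convention makes smoothing unhelpful on
  synthetic data (see above) — the opposite of typical real-spectra
  behavior — and slightly favors selectors over full-spectrum models.
* UVE's max-noise cutoff has limited null specificity at
  `noiseCount = 18` (see above).
* SPA is a greedy heuristic; its winning subset can be measurably worse
  than the best exhaustive subset of the same size.
* No preprocessing chains (methods are evaluated singly), no nonlinear
  models, and no calibration-transfer methods.
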