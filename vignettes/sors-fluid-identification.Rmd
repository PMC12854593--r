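---
title: "Through-container fluid identification with SORS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Through-container fluid identification with SORS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorsid)
```

This vignette documents the models, assumptions and design choices behind
`sorsid`. The package classifies preservation fluids inside sealed
containers from paired zero/offset spatially offset Raman (SORS)
measurements and types the container material from the complementary
"reverse SORS" signal.

## The two-layer measurement model

A SORS measurement of a fluid-filled jar is modelled as two linear mixtures
of a container spectrum $C(\nu)$ and a fluid spectrum $F(\nu)$:

$$I_0 = a_z C + b_z F + \varepsilon_0, \qquad
  I_\Delta = a_o C + b_o F + \varepsilon_\Delta,$$

with the *subsurface enrichment* constraint $b_o/a_o > b_z/a_z$: moving the
collection point away from the laser spot favours photons that travelled
through the wall into the fluid. All processing happens in the
750–1800 cm⁻¹ fingerprint window, where the solvents and additives of
preservation fluids have their informative bands.

### Scaling-factor estimation

The fluid is isolated as $I_\Delta - k_f I_0$ with $k_f$ chosen to cancel
the container ($k_f = a_o/a_z$ in the model). Only non-negativity
identifies $k_f$ from a single pair: the package takes the largest $k$
whose negativity penalty $P(k)=\sum_\nu \max(0, -(I_\Delta - k I_0))^2$
stays within a small tolerance (`sf_grid_rel_tol`, default $10^{-6}$ of the
penalty range) of the grid minimum — the knee where the subtraction stops
being physical. A windowed least-squares estimator over a user-specified
container-dominant interval (`sf_window`) is available as an alternative.

The knee can only find the nulling ratio of a layer that *dominates the
channels somewhere*. The container does (glass fluorescence and polymer
bands form a floor everywhere), so the forward estimate is accurate: on
noiseless glass-jar simulations the recovered fluid differs from the truth
by a cosine residual of order $10^{-4}$. The reverse factor
$k_r = b_z/b_o$, in contrast, is intrinsically ill-determined — the fluid
signature in the zero channel is buried under the container signal and
polynomial-baseline model error. The reverse knee therefore runs on
peak-clipped baseline-corrected channels (where fluid bands can dominate)
and is capped at $0.5/k_f$, which the enrichment constraint justifies and
which guarantees the container branch is never self-cancelled. The
container branch consequently tolerates a small fluid residue (recovery
cosine ≥ 0.99 rather than ≥ 0.999); its downstream use is material typing,
not quantification, and the curve-resolution step is insensitive at this
level.

### Baseline, normalization and container deflation

The fluid branch is baseline-corrected by iterative peak-clipping
polynomial fitting (order 5, 20 iterations: fit, replace points above the
fit by the fit, refit) and normalized by standard normal variate (SNV).
Negative excursions after subtraction are retained — clipping would bias
SNV.

Scaling-factor error leaves a small multiple of the container in the fluid
branch. For glasses this leakage is smooth and the polynomial baseline
absorbs it. Sharp polymer bands survive, so the fluid branch is also
produced in *deflated* representations: for each reference container
material, the polynomial-detail component of its rendered profile is
regressed out. Deflation is a fixed linear operator per material, so
calibration and query spectra remain comparable inside any one
representation. A sample is classified in the representation of its own
container — read off the reverse-SORS spectrum (detail-energy fraction
above 5% marks a polymer; cosine match against the family's references
names the material) — falling back to the plain representation when the
sample's container matches the one the calibration was measured through.
Removing a single known interference direction costs essentially no fluid
information; the one overlap worth noting (a PMMA band near the
formaldehyde 1241 cm⁻¹ marker) only affects samples in PMMA containers.

## Classification

PCA is fitted to the processed calibration spectra. Rather than retaining
PCs by explained variance — which ranks the (legitimate) within-class
concentration spread of classes specified as ranges, e.g. ethanol 70–80%,
above the tiny directions that separate a 1% formaldehyde admixture — the
package scores every pooled PC with a one-way analysis-of-variance *F*
statistic against the class labels, keeps the top `pca_select` (default 8)
of a pool capped at `pca_max_components` (default 40), and scales each by
its pooled within-class standard deviation. Euclidean k-nearest-neighbour
classification (*k* = 4, majority vote; ties broken by smaller mean
neighbour distance, then lexicographically) operates in these coordinates.
This mirrors standard chemometric practice of classifying on *significant*
rather than top-variance components, while remaining fully automated.

A query is rejected as `OUT_OF_SET` when its mean distance to its *k*
neighbours exceeds the 99th percentile of the calibration's leave-one-out
mean neighbour distances — a calibration-anchored threshold that needs no
external tuning. Fluids whose novel bands are nearly orthogonal to the
calibration subspace can evade this distance test if their in-subspace
shadow lands near a class; with an expected-fluid table supplied, such
samples are still reported `FAILED` through the truth-mismatch rule.

Outcome flags operationalize the √/?/× taxonomy: `FAILED` for out-of-set
rejection, truth contradiction, or no zero/offset contrast; `AMBIGUOUS`
when replicate-level labels disagree (the notes record whether the
disagreeing classes share a main excipient group) or the vote margin falls
below 10% of the mean neighbour distance; `MATCH` otherwise. Replicates are
processed individually, averaged, and re-normalized before the primary
classification; replicate order never affects the result.

## Container typing

Per-sample reverse-SORS spectra (replicate-averaged, min-shifted to
non-negativity rather than clipped) are stacked and factorized as
$X \approx CS$, $C, S \ge 0$, by alternating non-negative least squares
with a deterministic SVD-based non-negative start (tolerance $10^{-8}$ on
the relative reconstruction change, at most 2000 iterations;
non-convergence is flagged, not raised). Each exact NNLS half-step makes
the objective non-increasing. The inner solver is a fast-combinatorial
active-set NNLS that solves all right-hand sides sharing a passive set
together. Components are ordered by score mass, matched to rendered
reference materials by greedy best cosine without reuse, and each sample
takes the material of its highest-scoring component (exact ties are
`indeterminate`).

## Residual analysis

After classification, the best least-squares multiple (plus intercept) of
the assigned class-mean reference is subtracted from the sample spectrum.
Residual bands are local maxima whose height *and* prominence exceed
`residual_threshold` (default 5) times the median-absolute-deviation noise
scale; centres are refined by quadratic apex interpolation (well below the
2 cm⁻¹ axis step). This is how low-level additives reveal themselves — an
alcoholic Bouin's fluid classified as ethanol leaves picric-acid and
formaldehyde bands in the residual.

## The synthetic-data generator

The simulator renders pure components as pseudo-Voigt band sums
(unit-normalized), mixes them by volume fraction, and forms the two
channels with mixing weights 0.8/0.2 (zero) and 0.3/0.7 (offset) by
default. It emulates the features that make the real problem hard:

* 20 calibration recipes (C1–C13 as tabulated mock fluids — glycerol,
  ethanol, ethanol+methanol, ethanol+formaldehyde and formaldehyde series —
  plus artifact-defined stand-ins C14–C20 for named historical recipes
  whose full compositions are not published; the stand-ins are synthetic
  constructions, labelled as such);
* concentration ranges (e.g. ethanol 70–80%) realized per replicate by
  uniform jitter within the range;
* a concentration-dependent shift of the broad water band
  (−25 cm⁻¹ per unit co-solute fraction), emulating OH-polarizability
  band shifts in ethanol–water mixtures;
* three glass containers as broad fluorescence envelopes and three
  polymers (PMMA, LDPE, PP) as sharp band sets, scaled 3× and 1.5× the
  unit fluid respectively;
* shot noise (Poisson at 20000 pseudo-counts per unit intensity), additive
  read noise (σ = 0.003), random cubic drift (σ = 0.01) and a broad fluid
  fluorescence envelope (0.05) for aged, discoloured fluids;
* out-of-calibration fluids (Dowicil-based, formaldehyde + ethylene
  glycol, phenoxetol + formaldehyde, Bouin's variants, Kaiserling-like) in
  the default 46-sample cohort.

Two marker positions are anchored to well-known bands (methanol
1034 cm⁻¹, potassium acetate 926 cm⁻¹); all other band positions are
plausible fixed constants chosen for internal consistency, not a
literature line list. Component weighting is by volume fraction of
unit-normalized spectra: relative Raman cross-sections are *not* modelled,
which makes dilute-additive detection in the simulator somewhat harder
than in reality (water is a notoriously weak scatterer). Passing tests on
this generator therefore demonstrate the pipeline's mechanics and
robustness margins, not instrument-grade limits of detection; conversely,
real data bring axis miscalibration, cosmic rays and specimen
autofluorescence shapes the generator does not emulate.

## Numerical and design notes

* Axes must match exactly before any subtraction or averaging; the package
  raises an error rather than interpolating silently (`resample()` is the
  explicit step).
* Truncation is closed on both ends; the default simulation axis
  (600–1900 cm⁻¹, 2 cm⁻¹ step) keeps the analysis window away from edges.
* One scaling factor is estimated per replicate, not per sample.
* The degenerate-measurement guard flags a fluid branch below 2% of the
  offset channel's amplitude as "no offset contrast".
* Configuration files are YAML with `preprocess:` and `pipeline:` sections
  mirroring `preprocess_config()` and `run_config()`; unknown keys are
  rejected.
* Calibration archives are a single human-readable JSON document with
  full-precision numbers; identical seeds reproduce cohorts, archives and
  report CSVs byte-for-byte.
* Problem sizes used throughout the documentation and checks — 13 classes
  × 6 replicates for calibration, 46 cohort samples with 2 replicates —
  follow the scale of a realistic one-day collection survey.

## Known limitations

* With two replicates per sample and classes that differ by 1.5–2% of one
  additive (formaldehyde 4–5% versus 4% formaldehyde + 1.75% methanol),
  replicate-level disagreement on the adjacent class is expected in a few
  percent of samples; these are flagged `AMBIGUOUS` with the correct class
  usually still the prediction — the behaviour the √/?/× taxonomy is
  designed to surface, not hide.
* The out-of-set rule is distance-based only; a principled spectral
  residual (Q-statistic) check was evaluated and found uninformative at
  these noise levels because replicate averaging shrinks query residuals
  below the calibration's own.
* The reverse scaling factor is reported but should not be interpreted
  quantitatively (see above).
* Multi-offset SORS inversions, photon-transport simulation, wavelet or
  asymmetric-least-squares baselines, and classifiers beyond KNN are out
  of scope.
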