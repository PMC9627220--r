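---
title: "Spectrum-effect relationship screening: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-effect relationship screening: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfx)
```

## The problem

A herbal preparation is a mixture of dozens of constituents; bioassays
measure the mixture, not the parts. A *spectrum-effect relationship* screens
for the constituents that drive activity by correlating a chromatographic
fingerprint — the integrated areas of the common peaks across preparation
batches — with the bioassay outcomes measured on the same batches. Batches
prepared under deliberately varied extraction conditions differ in
composition; constituents whose abundance tracks an assay outcome across
batches are candidate actives.

The design emulated here is ten batches profiled over seventy common LC-MS
peaks, six effect endpoints (DPPH radical scavenging summarised as an IC50,
FRAP ferric-reducing power, and four cell-based anti-proliferation /
anti-migration endpoints on A549 cells), and three complementary screening
statistics whose per-endpoint selections are intersected into a consensus.

## Pipeline stages and their models

### Fingerprint construction and QC

`match_common_peaks()` groups peaks across batches by retention time
(single-linkage grouping per ion mode, consensus = median RT, default
tolerance 0.2 min) and requires exactly one peak per batch within the
tolerance; ambiguity is an error, absence excludes the peak from the common
set. Peaks are numbered `P1..Pn` by ion-mode block then consensus RT, fixed
at matrix construction so selections are comparable across methods.

QC metrics follow fingerprint-method convention: relative retention time
and relative peak area against a designated internal-standard peak
(`relative_to_is()`), percent RSD/CV with the sample (n−1) standard
deviation (`dispersion_stats()`; the population variant is a deliberate
non-choice — the convention is unstated in most method reports, and n−1 is
the conservative default). Linearity is assessed on a serial QC dilution
(default 2, 4, 8, 16, 32, 64-fold) by OLS of the analyte/IS area ratio on
relative concentration `1/dilution` — absolute constituent concentrations
are unknown, so inverse dilution is the only concentration proxy available —
and peaks with R² below 0.99 are removed before screening
(`linearity_screen()`).

Similarity of each batch to the reference fingerprint
(`fingerprint_similarity()`) is the uncentered cosine against the mean
fingerprint across batches. The legacy similarity software's exact algorithm
is unpublished; cosine against the mean chromatogram is its documented
default behaviour, and the reference construction is recorded in the result.
`write_legacy_fingerprint()` emits the two-block single-byte TXT exchange
layout (block 1: RT + intensity in elution order; block 2: height + area in
RT order); the column dialect is a documented reconstruction from a prose
description, flagged as such.

### Effect endpoints and orientation

Raw endpoints mix directions: a *lower* IC50, viability, healing rate or
transwell count means a *more* active batch, while a higher FRAP value does.
All three screening methods need a common orientation, so
`assemble_effects()` maps every endpoint onto an activity where larger =
more active:

| family | transform | rationale |
|---|---|---|
| IC50 | `1 / raw` | potency is inverse concentration; keeps positivity and exact rank reversal |
| concentration (FRAP) | identity | already oriented |
| percentage, lower-better | `100 − raw` | stays in (0, 100), exact reflection |
| count, lower-better | `(max + min) − raw` | range reflection, keeps positivity without an arbitrary constant |

This orientation step is a genuine gap-fill: screening studies state that
they select components "positively correlated" with activity but rarely say
how decreasing-better endpoints were oriented. The transform used is
recorded per endpoint in the effect table. Note that the reflections
introduce an arbitrary offset, which matters for grey relational analysis
(below).

Assay-level computations are standard: the DPPH scavenging-rate formula,
wound healing rate, OLS FRAP calibration with inversion, and a
four-parameter logistic dose-response fit on log concentration
(`fit_ic50()`, Levenberg–Marquardt least squares with a coarse grid
fallback for starting values; the IC50 is the concentration at the response
midway between the fitted asymptotes).

### Grey relational analysis

Deng's grey relational coefficient between the oriented activity `x0(k)`
and each peak's area profile `xi(k)`, with deltas `D_i(k) = |x0(k)−xi(k)|`
and the global minimum/maximum over *all* comparison sequences jointly:

$$\xi_i(k) = \frac{D_{min} + \rho D_{max}}{D_i(k) + \rho D_{max}}, \qquad
r_i = \frac{1}{N}\sum_k \xi_i(k)$$

with resolution coefficient ρ = 0.5 and selection rule `r > 0.8` (strict,
"over 0.8"). Two choices are open in the literature and are exposed as
options:

* **Normalisation.** Classical practice divides each sequence by its mean.
  That fails here by construction: the reflected activities
  (`100 − viability`, range-reflected counts) carry a large arbitrary
  offset and small relative dispersion, so after mean normalisation the
  reference is nearly constant and the deltas measure only each peak's own
  dispersion — the degree loses all tracking signal. The pipeline default is
  therefore the z-score (`gra_normalize(mode = "zscore")`), which is both
  scale- and offset-invariant; mean, min-max and none remain available.
* **Global vs per-sequence deltas.** The defining formula takes the double
  min/max over sequences and positions jointly; the global variant is the
  default. The per-sequence variant is self-normalising per peak and far
  less discriminative; it is provided for sensitivity analysis only.

### PLS regression with VIP

`pls_fit()` is a NIPALS PLS1 on autoscaled data; `vip_scores()` is Wold's
VIP (the normalisation identity ΣVIP² = p is asserted in tests to 1e−8, and
the whole decomposition is cross-checked against an independent
eigen-decomposition implementation and against `mixOmics::pls`).
Cross-validation (`cv_q2()`) is leave-one-out — with ~10 batches, k-fold
splits are unstable — and the component count is the smallest A whose Q² is
within 0.01 of the maximum over A ≤ 5 (additional components must earn
their keep; commercial defaults choose A differently, so reproduced Q²
values may differ at the second decimal). Selection requires VIP > 1 *and*
a positive regression coefficient, mirroring "positively correlated"; a
sign-agnostic mode exists for sensitivity analysis.

### BP-ANN with mean impact values

`train_ann()` is a p-3-1 feedforward regressor (sigmoidal hidden layer,
linear output) on min-max scaled inputs/output, trained by gradient descent
with a small weight decay (1e−3) for stability at n = 10. The mean impact
value (`miv_scores()`) perturbs each input column of the *original-scale*
data by ±10%, takes the per-sample prediction difference, and averages —
first over samples, then over an ensemble of 20 seeded restarts (each with
its own 8/2 train/test split). The ensemble is this implementation's answer
to initialisation noise: a single small network's MIV signs are unstable at
this sample size. Selection keeps MIV > 0. For an exactly linear model the
closed form `MIV_j = 0.2 · w_j · mean(x_j)` holds and is tested to 1e−6.

The network width follows the retained-peak count (59 after the default
linearity screen); a fixed seventy-input architecture is sometimes quoted
for this design, but feeding dropped peaks to the network would contradict
the screen, so retained-count is the default and the width simply follows
the supplied matrix.

### Consensus

Per endpoint, the consensus is the exact three-way intersection of the GRA,
PLSR and MIV selections (`intersect_per_effect()`); cross-endpoint overlaps
(`shared_across_effects()`) are pure set algebra on the per-endpoint
consensus sets. Reports (`screening_report()`) carry each method's full
score vector, not only the sets, so threshold sensitivity can be re-derived
without recomputation, and are deterministic JSON.

## The synthetic-data generator

`gen_spectrum_effect()` is first-class, tested code: it defines the
conditions every downstream claim is tested under.

* **Areas** are per-peak log-normal with locations `meanlog ~ U(2, 5)` and
  idiosyncratic scale `sdlog = 0.5` (CV ≈ 53%) — LC-MS areas are positive
  and right-skewed, and relative-peak-area CVs up to ~150% are on record
  for this kind of decoction fingerprint.
* **Planted actives co-vary.** The active peaks of an endpoint share a
  latent per-batch extraction factor with loading 1.0 on the log scale
  (≈80% shared log-variance; total active-peak CV ≈ 156%). This emulates
  constituents of a common herb or fraction whose yield moves together as
  decoction conditions vary. It is also what makes the screening problem
  well-posed: without co-variation, eight independent weak drivers of a
  ten-batch response cannot be individually recovered by any method.
  Default planted sets are disjoint across endpoints — a peak planted for
  two endpoints would respond to two independent factors and track neither
  cleanly; overlapping sets can still be planted explicitly.
* **Latent activity** is a positive linear combination of the planted
  peaks' (mean-normalised) areas (a saturating Michaelis–Menten variant is
  available), with multiplicative (CV-style) assay noise, default 5%.
* **Raw encodings** put each endpoint on its assay's native scale: IC50-like
  `a/L`, concentration-like `a·L + b`, and bounded decreasing
  `a·exp(−L/b)` for percentages and counts (a healing rate or cell count
  cannot cross zero, so the decreasing families saturate rather than go
  linear). Scale parameters were set once to match the magnitudes a
  ten-batch decoction experiment reports (IC50 ~1.6–5.5 mg/mL, FRAP
  ~150–900 µmol/L, viability ~20–85%, and so on).
* The internal standard is a non-active peak with near-zero dispersion (a
  spiked reference is nominally constant), and retention times sit on a
  jittered grid so common peaks stay separable at the default matching
  tolerance — real common peaks are resolved by definition.
* Identical spec + seed reproduce output bit for bit.

**What the generator does not emulate:** a global batch-concentration
factor shared by *all* peaks (available via `batch_effect`, off by
default), correlated null peaks, retention-time drift beyond jitter,
ion-suppression effects, and replicate-level assay structure (endpoints
enter as per-batch means; screening operates on means). Passing tests on
this generator therefore show that the statistics and their thresholds
behave as designed under a clean planted-truth model — not that the
defaults are optimal for any particular instrument or formulation.

## Recovery behaviour and a known limitation

On single-endpoint datasets at the design conditions (10 batches × 70
peaks, 8 planted actives, linear link, 5% noise), the three-method
consensus recovers planted actives with mean recall ≈ 0.9 and mean
precision ≈ 0.85 over 20 seeds (`scripts/acceptance.R` recomputes this).

Under the six-endpoint default generator, recovery is measured at roughly
0.86 recall / 0.91 precision. The binding constraint throughout is GRA at
the fixed 0.8 threshold: with six assays sharing one fingerprint, most
peaks carry *some* endpoint's extraction factor, the z-scored null
sequences become smoother, the global delta maximum shrinks, and grey
degrees concentrate just below the threshold for weakly-encoded endpoints
(the bounded saturating readouts lose part of the linear signal). PLS/VIP
and MIV retain planted peaks at ≈0.99 and ≈1.0 recall respectively, so the
consensus inherits GRA's misses. Users screening data with strongly
saturating readouts may wish to inspect the full GRA score table (always
reported) rather than rely on the 0.8 cut alone.

## Numerical choices and degenerate inputs

* Problem sizes in the tests and acceptance script (20 seeded datasets,
  ensembles of 20 restarts, 100-instance oracle sweeps) were chosen as the
  smallest sizes at which the stochastic checks are stable.
* Zero-variance predictors are dropped with a warning before PLS;
  zero-variance responses, zero-mean or constant sequences under the
  respective GRA normalisations, zero IS areas, degenerate calibration
  series and flat dose-response curves are errors with named culprits.
* `fit_ic50` accepts a negative Hill slope for decreasing curves; ties in
  the starting-value heuristic resolve to the first grid point.
* Grey coefficients at an exact-match delta of zero with a zero global
  minimum evaluate to 1 by convention (the formula's 0/0 at
  `rho·Dmax = 0` cannot occur for non-identical sequences).
* All randomness is seed-controlled; network ensembles offset the base
  seed per endpoint so endpoints do not share initialisations.
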