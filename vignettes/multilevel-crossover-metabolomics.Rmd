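---
title: "Multilevel sparse PLS-DA for crossover metabolomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel sparse PLS-DA for crossover metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmet)
```

## The problem

In a two-period crossover intervention every subject receives both the
active supplement (O) and placebo (P), separated by a washout, with
baseline (B) days opening each period. LC-MS metabolomics of such designs
faces a well-known obstacle: between-subject biological variation is far
larger than the metabolic shift caused by the intervention, so ordinary
PCA or PLS-DA of the pooled feature table clusters by *person*, not by
*treatment*. The remedy is a multilevel analysis: decompose the total
variation into additive components and remove the ones that obscure the
contrast of interest before fitting a discriminant model.

`crossmet` models the log-scale intensity of feature $f$ in the sample of
subject $s$ on day $d$ of week $w$ as

$$\log x_{swdf} = \mu_f + b_{sf} + v_{wf} + u_{wdf} +
  \mathbb{1}\{\text{O arm},\, f \in A\}\,\delta\, r_d + \varepsilon_{swdf},$$

where $b$, $v$, $u$, $\varepsilon$ are the between-subject, week, day and
analytical components, $A$ is the set of treatment-responsive features,
$\delta$ is the log-scale effect and $r_1,\dots,r_5 \in [0,1]$ is a
per-day modulation profile. The total variance is the sum of the
component variances; the synthetic generator (`generate_crossover()`)
draws each component explicitly and returns them, so every downstream
operation can be verified against exact ground truth.

## Variance removal and the multilevel model

`remove_variation(X, grouping)` performs the split
$X = (\bar X_g - \bar X) + (X - \bar X_g + \bar X)$: the between-group
part and a residual that keeps the grand mean (so raw-scale fold changes
remain meaningful downstream). For a subject grouping this is the
classical within-subject split used in multilevel omics analysis. The
between/within sums of squares are additive, which the tests check
against an explicit loop oracle.

`fit_mlsplsda()` composes this with a sparse PLS-DA: one discriminant
factor (e.g. phase P/O) gives the one-level model; two factors (e.g.
phase × day) give the two-level model through interaction labels.
Week- and day-based components may be removed marginally (default) or
nested within subject (`nested = TRUE`); the marginal form is the plainer
reading of "subtracting the week effect" and the two coincide on balanced
designs with shared week causes, which is how the generator draws them.
Interaction labels were chosen over a sequential two-response
decomposition because they keep the fitted object a single classifier
whose score plot can be read directly (day-wise centroids, below).

## The sparse PLS-DA core

`splsda_fit()` is a NIPALS PLS against the centred one-hot class matrix,
with a hard cardinality constraint: inside each component's inner loop
the X weight vector is thresholded to its `keepx[h]` largest-magnitude
entries (ties broken by smaller index, for determinism) and renormalised;
convergence tolerance is 1e-6 with at most 500 iterations. X is deflated
by regression on its scores; Y is not deflated, and scores are mutually
orthogonal. With `keepx = p` the first component equals the dominant
singular vector of the X–Y cross-covariance, which the tests verify
against an independent SVD oracle and against the mixOmics
implementation. Hard thresholding (rather than a penalty path) was chosen
because the tuning semantics of the analysis are expressed directly as
"variable selection sizes" (keepX = 50, 60, 70 per dimension).

Tuning (`splsda_tune()`) runs repeated stratified seven-fold
cross-validation over the keepX grid and reports two criteria: the mean
misclassification rate per component, and a correlation criterion — the
mean absolute Pearson correlation between cross-validation-predicted and
full-model component scores. The exact quantity behind a "maximum
correlation" tuning readout is not standardised; this definition is the
package's choice and is the one its outputs report. Prediction defaults
to `max_dist` (largest predicted one-hot score), with `centroids_dist`
available; `max_dist` is the conventional default for two-class PLS-DA.

`splsda_performance()` reports in-fit $R^2$ per component and
cross-validated $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$, plus overall and
balanced error rates. `splsda_vip()` implements the standard VIP with the
normalisation $\mathrm{mean}(\mathrm{VIP}^2) = 1$; the conventional
importance threshold used in the workflow is VIP > 1.5.

### Cross-validation folds in multilevel comparisons

One numerical subtlety deserves emphasis. With class-stratified folds on
paired crossover data, a *non*-subtracted model does not sit at chance —
it performs systematically **worse** than chance, because the held-out
samples of a subject complement the slight class imbalance of that
subject's training samples (an anti-learning artifact of paired designs).
The simulation comparisons of plain vs subject-subtracted models
therefore use folds that contain whole subjects (`cv_error_grouped` in
the test helpers and the acceptance script): the statistically meaningful
generalisation unit in multilevel data is the subject, and under
subject-grouped folds the plain model sits at chance (error ≈ 0.5) while
the multilevel model recovers the effect. The seven-fold stratified CV of
`splsda_tune()`/`splsda_performance()` follows the conventional
operational procedure and is kept for tuning within a fixed model
configuration.

## Preprocessing

The pipeline order is QC-RLSC → PPCA imputation → quotient normalisation
→ transform/scaling: drift is an acquisition artifact and is corrected
first, on the intensities as acquired; imputation precedes quotient
normalisation so that quotients are computed over complete vectors.

* **QC-RLSC** (`qc_rlsc()`): per feature, a robust tricube-weighted local
  linear regression (`stats::lowess`, default span 0.75 — the common
  QC-RLSC default) of pooled-QC intensities on injection order, evaluated
  everywhere by linear interpolation with constant edge extrapolation;
  intensities are divided by the fitted curve normalised to its QC
  median. Local linear fits reproduce straight lines exactly, so
  generator-applied linear drift is removed to machine precision.
* **PPCA imputation** (`impute_ppca()`): EM for the probabilistic PCA
  model in its zero-noise limit — iterative truncated-SVD reconstruction
  with feature means re-estimated from the completed matrix at every
  step, missing cells replaced by their conditional expectation. The
  zero-noise limit is used because it makes imputation exact on low-rank
  data (the contract the tests enforce) and is deterministic. The
  pipeline imputes on the log scale, where the low-rank model is
  appropriate for log-normal intensities and the back-transformed values
  are guaranteed positive. Observed cells are never altered.
* **Quotient normalisation** (`normalize_reference()`): pseudo-reference
  = feature-wise mean of the control-group samples (baseline + placebo —
  the only non-treated set); per-sample quotient = median intensity ratio
  to the reference. The quotient computation is iterated to its fixed
  point, anchored so the reference samples' geometric-mean quotient is 1.
  The first iteration is classical single-pass PQN; the fixed point makes
  the operation exactly idempotent, so re-running a pipeline stage cannot
  change a normalised table.
* **Transform/scaling** (`transform_scale()`): log10 then unit-variance
  autoscaling by default. The upstream choice is not dictated by the
  workflow tooling; autoscaling is the common default for sPLS-DA and
  pareto scaling is available.

Consensus matching of two peak-picker outputs
(`consensus_features()`) uses greedy one-to-one closest-pair matching
under ppm and retention-time windows, with deterministic tie-breaking —
the Venn arithmetic of common and picker-unique features, verified
against a brute-force all-pairs oracle.

## Candidate selection and validation

Two selection strategies are implemented: the top-`k` absolute loadings
per component in component-major order (`select_top_loadings()`, default
k = 10), and the adjustable-radius correlation circle
(`select_by_radius()`): features whose correlations with components 1
and 2 have norm between a shrinking radius (start 0.9, step 0.1) and the
unit circle, the outer boundary being the correlation circle itself
(coordinates are correlations, bounded by 1, which is how the "outer
ellipse" is interpreted here). Validation uses subject-paired two-sided
t-tests on per-subject log-mean intensities with Benjamini–Hochberg
q-values; the paired t-test is the two-arm special case of the
repeated-measures ANOVA conventionally cited for such data. Fold changes
are subject-wise O/P ratios on the raw scale, reported as mean ± SD over
subjects, with downregulated features reported as the reciprocal so all
printed fold changes are ≥ 1 and the trend arrow carries the direction.

## Ion annotation

`ion_mz()`, `monoisotopic_mass()`, `ppm_error()` and `rdb_equivalents()`
reproduce the computed columns of a candidate-metabolite table:
monoisotopic masses from standard reference isotope masses (H 1.007825,
C 12, N 14.003074, O 15.994915, S 31.972071, P 30.973762; proton
1.0072765), adduct m/z for [M±H] and proton-bound dimers, the signed ppm
convention (observed − theoretical)/theoretical, and
ring-and-double-bond equivalents of the ion formula
(C − H/2 + N/2 + P/2 + 1), which are half-integers for even-electron
ions of chemically valid neutral formulas.

## The synthetic generator: what it does and does not emulate

Defaults encode the study conditions: 9 subjects, 2 weeks, 2 baseline +
5 administration days (126 samples per biofluid), pooled-QC injections
(5 lead, 1 per 10 samples, 5 tail), linear injection-order drift,
5% missing cells, 300 features of which 10% respond with a log-scale
effect of log(1.8) modulated by the day profile (1, 0.9, 0.7, 0.4, 0.1)
— a decaying profile that reproduces the qualitative "metabolome reset":
the O–P separation shrinks over administration days and day-5 treated
samples approach placebo. Between-subject SD 0.8 dominates week (0.3),
day (0.15) and analytical (0.2) SDs, matching the qualitative ordering
reported for such designs; none of these magnitudes is prescribed by the
underlying study, so they are package defaults chosen once as realistic
for LC-MS serum/urine profiling, with between-subject variation
dominating the treatment effect.

What the generator does **not** emulate: chromatographic peak shapes,
isotope patterns and in-source fragmentation, correlated feature blocks
(pathway structure), multi-batch effects, or heteroscedastic noise.
Passing tests therefore demonstrate correctness of the algorithms under
the stated additive log-normal model, not performance on any particular
real dataset.

## Problem sizes and numerical choices

Simulation-based checks run at deliberately modest sizes chosen to make
the statistical properties sharp while keeping the whole suite fast:
oracle equivalence on 50×50 matrices; multilevel-benefit comparisons on
100 features (10 affected, effect 0.4, between-subject SD 4) over 20
seeds; support recovery on 500 features with 50 planted (within-pair
Cohen's d ≈ 3) over 20 seeds; null calibration on 60×100 pure-noise
matrices. Degenerate inputs are handled explicitly: all-missing features,
single-class labels, zero-variance features (skipped in scaling),
non-positive drift or QC fits (feature left uncorrected with a warning),
empty peak lists (empty consensus, not an error), and exact fold-change
ties (trend "down", flagged).

## Known limitations

* Variance components are removed by group-mean centring, not estimated
  by REML/mixed models; unbalanced designs lose exact SS additivity
  between successively removed factors.
* The correlation tuning criterion is a package definition (see above).
* PPCA's zero-noise EM can overfit the missing cells when the chosen
  rank exceeds the true signal rank; the pipeline default (3 components)
  is conservative for 126-sample tables.
* Fold changes assume the raw scale is meaningful after normalisation;
  pooled-group (rather than subject-mean) ratios are not provided.
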