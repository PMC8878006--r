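# crossmet

Multilevel sparse PLS-DA analysis of crossover-design LC-MS metabolomics.

In a two-period crossover intervention each subject receives both the
active treatment (O) and placebo (P), with baseline days (B) opening each
week. Between-subject biological variation typically dwarfs the treatment
effect, so ordinary PCA/PLS-DA of the feature table clusters by person,
not treatment. `crossmet` implements the multilevel workflow for this
situation, end to end:

* **Data model & I/O** — feature tables (samples × features with per-feature
  m/z and retention time) and crossover sample metadata, CSV round trips
  that preserve missingness, and crossover balance validation.
* **Synthetic study generator** — log-normal intensities built from an
  explicit additive decomposition
  `Var = Σ(Var_within + Var_between + Var_week + Var_day + Var_analytical)`,
  with known affected features, a per-day effect profile (which can encode a
  "metabolome reset" where day-5 treated samples return to placebo), pooled
  QC injections, linear signal drift and missing values — so every stage is
  testable against exact ground truth.
* **Preprocessing** — consensus matching of two peak-picker outputs (the
  Venn arithmetic), QC-based robust loess signal-drift correction
  (QC-RLSC), probabilistic-PCA missing-value imputation, probabilistic
  quotient normalisation against a control-group pseudo-reference, log10 +
  autoscaling.
* **Multilevel sPLS-DA** — removal of a chosen variance component
  (between-subject, week or day) by group-mean centring, one-level (P vs O)
  and two-level (e.g. phase × day) discriminant models on the residual; a
  from-scratch sparse PLS-DA core with per-component keepX constraints,
  seven-fold cross-validated tuning (error and score-correlation criteria),
  VIP, and R²/Q² performance.
* **Candidate selection & validation** — top-loadings and
  adjustable-radius correlation-circle strategies, subject-paired t-tests
  with Benjamini–Hochberg FDR, and subject-wise fold changes (mean ± SD,
  reciprocal convention for downregulated features).
* **Ion annotation** — molecular-formula parsing, monoisotopic masses,
  [M±H]/[2M±H] adduct m/z, signed ppm errors and ring-and-double-bond
  equivalents of the ion formula.

## Worked example

The `analysis/` directory is the narrative workflow (each script reads
the previous script's outputs from `results/`):

```sh
Rscript analysis/01_simulate.R          # 126-sample crossover study + QCs
Rscript analysis/02_preprocess.R        # QC-RLSC, PPCA, PQN, scaling
Rscript analysis/03_variance_structure.R
Rscript analysis/04_multilevel_models.R
Rscript analysis/05_select_and_validate.R
Rscript analysis/06_annotate.R
```

Output of `03_variance_structure.R` — between-subject variation dominates,
which is why the plain model fails:

```
share of total sum of squares explained by each factor:
  factor ss_share
 subject   0.8046
    week   0.0691
     day   0.0213
9-subject model (8 components) training error: 0.000
```

Output of `04_multilevel_models.R` — subtracting the between-subject
variation exposes the treatment effect (CV errors over the keepX grid
50/60/70), and the two-level phase × day model shows the day-5 retraction
of treated samples toward placebo:

```
subtract subject: CV error (comp1) 0.20/0.22/0.24 | correlation 0.97/0.96/0.95
subtract week   : CV error (comp1) 0.48/0.51/0.54 | correlation 0.65/0.56/0.48
subtract day    : CV error (comp1) 0.49/0.51/0.53 | correlation 0.58/0.52/0.46
one-level (subtract subject): R2 0.60/0.66, Q2 0.50/0.57, BER 0.133
O-vs-P centroid gap on component 1 by administration day:
 day o_minus_p_gap
   1         3.948
   2         3.699
   3         2.742
   4         1.311
   5         0.776
```

Output of `05_select_and_validate.R` — the two selection strategies, FDR
validation and fold changes with ground-truth bookkeeping:

```
strategy 1 (top loadings): 20 features; strategy 2 (radius 0.8): 38
selected 48 candidates; 6 FDR-significant; 15/30 planted features recovered
VIP > 1.5: 33 features (29 truly affected)
```

`06_annotate.R` recomputes the annotation arithmetic for reference ions,
e.g. protonated tryptophan (C11H12N2O2): exact mass 204.0899, theoretical
m/z 205.0972, RDB 6.5.

The same chain is available programmatically:

```r
library(crossmet)
run_pipeline(default_config(seed = 1), out_dir = "run1")
```

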