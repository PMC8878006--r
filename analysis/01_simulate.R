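#!/usr/bin/env Rscript
# Simulate the crossover study: 9 subjects x 2 weeks x (2 baseline + 5
# administration) days, pooled-QC injections, linear signal drift and
# missing values. Writes the raw feature table, design and ground truth.
suppressPackageStartupMessages(library(crossmet))

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

spec <- synthetic_spec(seed = seed)   # study defaults: 300 features, 10% affected
g <- generate_crossover(spec)
stopifnot(validate_crossover(g$design)$balance_ok)

qc <- make_qc_series(g$table, g$design, qc_every = 10, n_lead = 5, n_tail = 5)
tab <- apply_drift(qc$table, qc$design, spec$drift_slope)
tab <- inject_missing(tab, spec$missing_rate, "mcar", seed = seed + 1L)

write_feature_table(tab, file.path(out, "raw_features.csv"))
write_design(qc$design, file.path(out, "design.csv"))
jsonlite::write_json(list(affected_feature_ids = g$truth$affected_feature_ids,
                          seed = seed),
                     file.path(out, "ground_truth.json"), auto_unbox = FALSE)

cat(sprintf("study: %d study samples + %d QC injections, %d features\n",
            sum(!qc$design$is_qc), sum(qc$design$is_qc),
            length(tab$feature_ids)))
cat(sprintf("missing cells: %d (%.1f%%)\n", sum(is.na(tab$intensities)),
            100 * mean(is.na(tab$intensities))))
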