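#!/usr/bin/env Rscript
# Preprocess the simulated run: QC-RLSC drift correction, PPCA imputation
# (log scale), quotient normalisation against a baseline+placebo
# pseudo-reference, then log10 + autoscaling for modelling.
suppressPackageStartupMessages(library(crossmet))

inp <- "results/01_simulate"
out <- "results/02_preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- load_feature_table(file.path(inp, "raw_features.csv"))
design <- load_design(file.path(inp, "design.csv"))

qrows <- design$sample_id[design$is_qc]
rsd <- function(X) apply(X, 2, function(x) sd(x, na.rm = TRUE) /
                           mean(x, na.rm = TRUE))
pre_rsd <- median(rsd(tab$intensities[qrows, ]), na.rm = TRUE)

corrected <- qc_rlsc(tab, design, span = 0.75)
post_rsd <- median(rsd(corrected$intensities[qrows, ]), na.rm = TRUE)
cat(sprintf("QC median RSD: %.2f%% before, %.2f%% after drift correction\n",
            100 * pre_rsd, 100 * post_rsd))

logimp <- impute_ppca(log(corrected$intensities), n_components = 3)
study <- design$sample_id[!design$is_qc]
imputed <- feature_table(exp(logimp)[study, ], corrected$feature_meta)
cat(sprintf("imputed %d missing cells by PPCA (3 components)\n",
            sum(is.na(corrected$intensities[study, ]))))

ref_ids <- design$sample_id[!design$is_qc &
                            design$phase %in% c("baseline", "placebo")]
normalized <- normalize_reference(imputed, ref_ids)
scaled <- transform_scale(normalized, transform = "log10",
                          scaling = "unit_variance")

write_feature_table(normalized, file.path(out, "normalized.csv"))
write_feature_table(scaled, file.path(out, "scaled.csv"))
cat("wrote normalized and scaled tables\n")
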