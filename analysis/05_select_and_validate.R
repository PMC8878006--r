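#!/usr/bin/env Rscript
# Candidate-metabolite selection from the one-level model by both
# strategies (top loadings per component; adjustable-radius correlation
# circle), VIP scoring, FDR-corrected paired validation and fold changes.
suppressPackageStartupMessages(library(crossmet))

out <- "results/05_selection"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scaled <- load_feature_table("results/02_preprocess/scaled.csv", validate = FALSE)
normalized <- load_feature_table("results/02_preprocess/normalized.csv")
design <- load_design("results/01_simulate/design.csv")
truth <- jsonlite::read_json("results/01_simulate/ground_truth.json",
                             simplifyVector = TRUE)

labels <- encode_classes(design, "phase")
X <- scaled$intensities[names(labels), ]
d <- design[match(names(labels), design$sample_id), ]
Xml <- remove_variation(X, d$subject)$residual
model <- splsda_fit(Xml, labels, n_components = 2, keepx = c(50, 50))

s1 <- select_top_loadings(model, k_per_component = 10)
s2 <- select_by_radius(model, Xml, start = 0.9, step = 0.1, floor = 0.5,
                       target_count = 20)
cat(sprintf("strategy 1 (top loadings): %d features; strategy 2 (radius %.1f): %d\n",
            nrow(s1), attr(s2, "radius_used"), nrow(s2)))
write.csv(s1, file.path(out, "top_loadings.csv"), row.names = FALSE)
write.csv(s2, file.path(out, "radius_selection.csv"), row.names = FALSE)

sel <- data.frame(feature_id = union(s1$feature_id, s2$feature_id))
rep <- selection_report(sel, model, normalized, design)
rep$significant <- !is.na(rep$q_value) & rep$q_value < 0.05
rep$truly_affected <- rep$feature_id %in% truth$affected_feature_ids
write.csv(rep, file.path(out, "selection_report.csv"), row.names = FALSE)

vip <- splsda_vip(model)
write.csv(data.frame(feature_id = names(vip), vip = vip),
          file.path(out, "vip.csv"), row.names = FALSE)

cat(sprintf("selected %d candidates; %d FDR-significant; %d/%d planted features recovered\n",
            nrow(rep), sum(rep$significant),
            sum(rep$truly_affected), length(truth$affected_feature_ids)))
cat(sprintf("VIP > 1.5: %d features (%d truly affected)\n",
            sum(vip > 1.5),
            sum(names(vip)[vip > 1.5] %in% truth$affected_feature_ids)))
cat("top of the candidate table (fold change is O/P or its reciprocal for down-trends):\n")
print(utils::head(rep[order(rep$q_value),
                      c("feature_id", "mz", "rt", "q_value", "fold_change",
                        "sd", "trend", "vip", "truly_affected")], 8),
      row.names = FALSE, digits = 3)
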