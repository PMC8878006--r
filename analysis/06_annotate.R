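#!/usr/bin/env Rscript
# Formula-based annotation of selected features against the bundled
# candidate metabolite list (adduct m/z, ppm error, RDB, exact mass), and
# a worked reproduction of the candidate-table arithmetic for reference
# metabolites.
suppressPackageStartupMessages(library(crossmet))

out <- "results/06_annotation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rep <- read.csv("results/05_selection/selection_report.csv")
cand <- load_candidates(system.file("extdata", "candidate_metabolites.csv",
                                    package = "crossmet"))

# simulated m/z values are random, so hits here only demonstrate the
# matching machinery on the analysis output
ann <- do.call(rbind, lapply(seq_len(nrow(rep)), function(i) {
  hits <- annotate_feature(rep$mz[i], "positive", cand, tol_ppm = 10)
  if (nrow(hits)) cbind(feature_id = rep$feature_id[i], hits) else NULL
}))
n_hits <- if (is.null(ann)) 0L else nrow(ann)
cat(sprintf("annotation hits among %d selected features at 10 ppm: %d\n",
            nrow(rep), n_hits))
if (!is.null(ann))
  write.csv(ann, file.path(out, "annotations.csv"), row.names = FALSE)

# reference arithmetic: recompute the printed columns for known ions
ref <- data.frame(
  name = c("L-tryptophan", "2-octenoylcarnitine", "Decanoylcarnitine",
           "L-glutamine", "Estrone sulfate"),
  formula = c("C11H12N2O2", "C15H27NO4", "C17H33NO4", "C5H10N2O3",
              "C18H22O5S"),
  adduct = c("[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M-H]-"),
  observed = c(205.0970, 286.2012, 316.2481, 147.0760, 349.1121))
ref$exact_mass <- round(sapply(ref$formula, monoisotopic_mass), 4)
ref$theoretical_mz <- round(mapply(ion_mz, ref$formula, ref$adduct), 4)
ref$delta_ppm <- round(ppm_error(ref$observed, ref$theoretical_mz), 1)
ref$rdb <- mapply(rdb_equivalents, ref$formula, ref$adduct)
write.csv(ref, file.path(out, "reference_ions.csv"), row.names = FALSE)
print(ref, row.names = FALSE)
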