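# Shared fixtures and independent oracles used across the suite.

# a tiny, fully deterministic feature table
tiny_table <- function(n_samples = 4, n_features = 3, seed = 11) {
  set.seed(seed)
  X <- matrix(round(exp(rnorm(n_samples * n_features, 8, 1)), 3),
              n_samples, n_features,
              dimnames = list(paste0("S", seq_len(n_samples)),
                              paste0("F", seq_len(n_features))))
  meta <- data.frame(feature_id = colnames(X),
                     mz = round(seq(100, 500, length.out = n_features), 4),
                     rt = round(seq(1, 10, length.out = n_features), 2),
                     polarity = "positive")
  feature_table(X, meta)
}

# brute-force greedy closest-pair consensus matcher (loop form, kept
# deliberately independent of the vectorised implementation)
oracle_consensus <- function(a, b, ppm_tol, rt_tol) {
  cand <- data.frame(i = integer(0), j = integer(0), dist = numeric(0),
                     dppm = numeric(0))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    dppm <- abs(a$mz[i] - b$mz[j]) / a$mz[i] * 1e6
    drt <- abs(a$rt[i] - b$rt[j])
    if (dppm <= ppm_tol && drt <= rt_tol) {
      cand <- rbind(cand, data.frame(
        i = i, j = j, dist = sqrt((dppm / ppm_tol)^2 + (drt / rt_tol)^2),
        dppm = dppm))
    }
  }
  cand <- cand[order(cand$dist, cand$dppm, cand$i, cand$j), , drop = FALSE]
  ua <- rep(FALSE, nrow(a)); ub <- rep(FALSE, nrow(b))
  n_common <- 0L
  for (k in seq_len(nrow(cand))) {
    if (!ua[cand$i[k]] && !ub[cand$j[k]]) {
      ua[cand$i[k]] <- TRUE; ub[cand$j[k]] <- TRUE
      n_common <- n_common + 1L
    }
  }
  list(n_common = n_common, n_unique_a = sum(!ua), n_unique_b = sum(!ub))
}

# subject-grouped M-fold CV error of a one-component sparse PLS-DA;
# folds contain whole subjects so paired-design leakage cannot occur
cv_error_grouped <- function(X, y, subjects, keepx, n_folds = 7, seed = 1,
                             n_components = 1) {
  set.seed(seed)
  us <- sample(unique(subjects))
  fold <- setNames(rep(seq_len(n_folds), length.out = length(us)), us)[subjects]
  wrong <- 0
  for (k in seq_len(n_folds)) {
    m <- splsda_fit(X[fold != k, , drop = FALSE], y[fold != k],
                    n_components, keepx = keepx)
    wrong <- wrong + sum(predict(m, X[fold == k, , drop = FALSE]) != y[fold == k])
  }
  wrong / length(y)
}

# multilevel-ready matrix from a generated study: log, autoscale, restrict
# to administration-day placebo/active samples
prep_admin_matrix <- function(g) {
  lab <- encode_classes(g$design, "phase")
  X <- scale(log(g$table$intensities[names(lab), , drop = FALSE]))
  d <- g$design[match(names(lab), g$design$sample_id), , drop = FALSE]
  list(X = X, labels = lab, design = d)
}
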