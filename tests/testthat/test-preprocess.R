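test_that("consensus matching agrees with a brute-force oracle", {
  # identical lists
  a <- peak_list(mz = c(100, 200, 300), rt = c(1, 2, 3))
  res <- consensus_features(a, a, ppm_tol = 5, rt_tol = 0.1)
  expect_identical(res$n_common, 3L)
  expect_identical(res$n_unique_a + res$n_unique_b, 0L)

  # 5 ppm apart: common at 10 ppm tolerance, unique at 1 ppm
  a1 <- peak_list(100.0000, 1.0)
  b1 <- peak_list(100.0005, 1.0)
  expect_identical(consensus_features(a1, b1, 10, 0.5)$n_common, 1L)
  r1 <- consensus_features(a1, b1, 1, 0.5)
  expect_identical(r1$n_common, 0L)
  expect_identical(r1$n_unique_a, 1L)
  expect_identical(r1$n_unique_b, 1L)

  # randomised lists vs the loop oracle, several tolerance regimes
  set.seed(21)
  for (rep in 1:5) {
    a <- peak_list(runif(50, 100, 110), runif(50, 0, 5))
    b <- peak_list(runif(50, 100, 110), runif(50, 0, 5))
    for (tol in list(c(50, 0.2), c(500, 1))) {
      got <- consensus_features(a, b, tol[1], tol[2])
      want <- oracle_consensus(a, b, tol[1], tol[2])
      expect_identical(got$n_common, want$n_common)
      expect_identical(got$n_unique_a, want$n_unique_a)
      expect_identical(got$n_unique_b, want$n_unique_b)
      # category counts sum to merged size
      expect_identical(got$n_common + got$n_unique_a + got$n_unique_b,
                       nrow(got$merged))
      # swapping inputs swaps the unique counts
      swp <- consensus_features(b, a, tol[1], tol[2])
      expect_identical(swp$n_unique_a, got$n_unique_b)
      expect_identical(swp$n_unique_b, got$n_unique_a)
    }
  }

  empty <- consensus_features(peak_list(numeric(0), numeric(0)),
                              peak_list(numeric(0), numeric(0)), 5, 0.1)
  expect_identical(empty$n_common, 0L)
})

test_that("consensus summary reports rounded percentages of the total", {
  s <- summarize_consensus(n_common = 887, n_unique_a = 203, n_unique_b = 402)
  expect_identical(s$total, 1492)
  expect_identical(unname(s$pct_unique_b), 27)
  s1 <- summarize_consensus(n_common = 1, n_unique_a = 0, n_unique_b = 0)
  expect_identical(unname(s1$pct_common), 100)
  expect_error(summarize_consensus(n_common = 0, n_unique_a = 0,
                                   n_unique_b = 0), "empty")
})

test_that("PPCA imputation recovers structure and never touches observed cells", {
  ft <- tiny_table()
  expect_identical(impute_ppca(ft, n_components = 2), ft)  # nothing missing

  # noiseless rank-2 matrix: deleted cells recovered to 1e-6 relative
  set.seed(31)
  U <- matrix(rnorm(30 * 2), 30, 2)
  V <- matrix(rnorm(2 * 20), 2, 20)
  M <- U %*% V + 10
  mask <- matrix(runif(length(M)) < 0.1, nrow(M))
  Mmiss <- M; Mmiss[mask] <- NA
  imp <- impute_ppca(Mmiss, n_components = 2, max_iter = 5000, tol = 1e-12)
  expect_lt(max(abs(imp[mask] - M[mask]) / abs(M[mask])), 1e-6)
  expect_identical(imp[!mask], M[!mask])

  # with noise, beats feature-mean imputation on the same mask
  Mn <- M + matrix(rnorm(length(M), 0, 0.3), nrow(M))
  Mn_miss <- Mn; Mn_miss[mask] <- NA
  imp2 <- impute_ppca(Mn_miss, n_components = 2)
  mu <- colMeans(Mn_miss, na.rm = TRUE)
  mean_imp <- Mn_miss
  for (j in seq_len(ncol(mean_imp))) mean_imp[is.na(mean_imp[, j]), j] <- mu[j]
  rmse <- function(A) sqrt(mean((A[mask] - Mn[mask])^2))
  expect_lt(rmse(imp2), rmse(mean_imp))

  # all-missing feature is refused by name
  bad <- Mmiss; bad[, 3] <- NA
  colnames(bad) <- paste0("F", 1:20)
  expect_error(impute_ppca(bad, n_components = 2), "F3")
})

test_that("quotient normalisation obeys its identities and is idempotent", {
  set.seed(41)
  p <- 51
  ref_row <- exp(rnorm(p, 8, 1))
  X <- rbind(ref1 = ref_row, ref2 = ref_row,          # identical references
             same = ref_row,                          # quotient 1
             twice = 2 * ref_row,                     # quotient 2
             mixed = ref_row * 3)                     # quotient 3
  X["mixed", 1:5] <- exp(rnorm(5, 8, 1))              # 10% contaminated
  meta <- data.frame(feature_id = paste0("F", 1:p), mz = 1:p + 100, rt = 1:p)
  colnames(X) <- meta$feature_id
  ft <- feature_table(X, meta)
  norm <- normalize_reference(ft, c("ref1", "ref2"))
  expect_equal(norm$intensities["same", ], X["same", ], tolerance = 1e-12)
  expect_equal(norm$intensities["twice", ], X["twice", ] / 2, tolerance = 1e-12)
  # median robustness: quotient 3 despite 10% contamination
  expect_equal(unname(norm$intensities["mixed", 6]), unname(X["mixed", 6] / 3),
               tolerance = 1e-12)

  # idempotence on generic data
  set.seed(42)
  G <- matrix(exp(rnorm(12 * p, 8, 1)), 12, p,
              dimnames = list(paste0("S", 1:12), meta$feature_id))
  gft <- feature_table(G, meta)
  once <- normalize_reference(gft, paste0("S", 1:5))
  twice <- normalize_reference(once, paste0("S", 1:5))
  expect_equal(twice$intensities, once$intensities, tolerance = 1e-12)
})

test_that("QC-RLSC removes linear drift and leaves constant signal alone", {
  spec <- synthetic_spec(n_features = 20, sigma_error = 0.1,
                         missing_rate = 0, seed = 51)
  g <- generate_crossover(spec)
  qc <- make_qc_series(g$table, g$design)
  drifted <- apply_drift(qc$table, qc$design, 0.01)

  corrected <- qc_rlsc(drifted, qc$design, span = 0.75)
  qrows <- qc$design$sample_id[qc$design$is_qc]
  rsd <- apply(corrected$intensities[qrows, ], 2, function(x) sd(x) / mean(x))
  expect_lt(max(rsd) * 100, 1)  # post-correction QC RSD < 1%

  # correction undoes the applied drift up to a per-feature constant
  ratio <- corrected$intensities / qc$table$intensities
  per_feature_spread <- apply(ratio, 2, function(r) diff(range(r)) / mean(r))
  expect_lt(max(per_feature_spread), 1e-6)

  # constant signal: correction factor is 1 everywhere
  const <- feature_table(matrix(100, nrow(qc$table$intensities), 3,
                                dimnames = list(qc$table$sample_ids,
                                                paste0("F", 1:3))),
                         data.frame(feature_id = paste0("F", 1:3),
                                    mz = 1:3 + 100, rt = 1:3))
  cc <- qc_rlsc(const, qc$design)
  expect_equal(cc$intensities, const$intensities, tolerance = 1e-12)

  few <- qc$design[!qc$design$is_qc, ]
  expect_error(qc_rlsc(g$table, study_design(as.data.frame(few))), "4 QC")
})

test_that("transform and scaling produce the stated column properties", {
  ft <- tiny_table(n_samples = 20, n_features = 6)
  cen <- transform_scale(ft, "none", "none")
  expect_lt(max(abs(colMeans(cen$intensities))), 1e-12)
  uv <- transform_scale(ft, "none", "unit_variance")
  expect_equal(unname(apply(uv$intensities, 2, sd)), rep(1, 6),
               tolerance = 1e-9)
  par <- transform_scale(ft, "none", "pareto")
  s0 <- apply(scale(ft$intensities, scale = FALSE), 2, sd)
  expect_equal(unname(apply(par$intensities, 2, sd)), unname(sqrt(s0)),
               tolerance = 1e-9)

  ft0 <- tiny_table()
  ft0$intensities[1, 1] <- 0
  expect_error(transform_scale(ft0, "log10", "none"), "non-positive")
})
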