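test_that("degenerate generator returns exact feature baselines", {
  spec <- synthetic_spec(n_features = 10, n_affected = 0, effect_size = 0,
                         sigma_between = 0, sigma_week = 0, sigma_day = 0,
                         sigma_error = 0, missing_rate = 0, seed = 3)
  g <- generate_crossover(spec)
  expected <- matrix(exp(g$truth$baseline), nrow(g$table$intensities),
                     10, byrow = TRUE)
  expect_equal(unname(g$table$intensities), expected, tolerance = 0)
})

test_that("log intensities equal the sum of ground-truth components exactly", {
  g <- generate_crossover(synthetic_spec(n_features = 40, seed = 5))
  lx <- log(g$table$intensities)
  rec <- sweep(g$truth$subject_offset + g$truth$week_offset +
               g$truth$day_offset + g$truth$treatment + g$truth$noise,
               2, g$truth$baseline, "+")
  expect_equal(unname(lx), unname(rec), tolerance = 1e-12)
})

test_that("default layout yields 126 balanced samples, deterministically", {
  spec <- synthetic_spec(n_features = 8)
  g1 <- generate_crossover(spec)
  g2 <- generate_crossover(spec)
  expect_identical(nrow(g1$design), 126L)
  expect_true(validate_crossover(g1$design)$balance_ok)
  expect_identical(g1$table$intensities, g2$table$intensities)
  expect_identical(as.data.frame(g1$design), as.data.frame(g2$design))
})

test_that("between-subject sum of squares matches its theoretical share", {
  spec <- synthetic_spec(n_features = 2000, n_affected = 0,
                         sigma_between = 1.0, sigma_week = 0.1,
                         sigma_day = 0.1, sigma_error = 0.1, seed = 8)
  g <- generate_crossover(spec)
  comp <- g$truth
  ss <- c(between = sum(scale(comp$subject_offset, scale = FALSE)^2),
          week = sum(scale(comp$week_offset, scale = FALSE)^2),
          day = sum(scale(comp$day_offset, scale = FALSE)^2),
          noise = sum(scale(comp$noise, scale = FALSE)^2))
  frac <- ss[["between"]] / sum(ss)
  theo <- 1 / (1 + 0.01 + 0.01 + 0.01)
  expect_lt(abs(frac - theo) / theo, 0.10)
})

test_that("QC series follows the lead/interior/tail injection scheme", {
  g <- generate_crossover(synthetic_spec(n_features = 6))
  # trim to exactly 100 study samples to mirror the canonical scheme
  keep <- g$design$sample_id[1:100]
  tab <- feature_table(g$table$intensities[keep, ], g$table$feature_meta)
  des <- study_design(as.data.frame(g$design[g$design$sample_id %in% keep, ]))
  qc <- make_qc_series(tab, des, qc_every = 10, n_lead = 5, n_tail = 5)
  expect_identical(sum(qc$design$is_qc), 20L)
  expect_identical(nrow(qc$design), 120L)
  expect_identical(qc$design$injection_order, 1:120)
  # QC rows equal the pooled feature means to machine precision
  pool <- colMeans(tab$intensities)
  qrows <- qc$table$intensities[qc$design$sample_id[qc$design$is_qc], ]
  expect_equal(unname(qrows), matrix(pool, 20, 6, byrow = TRUE),
               tolerance = 1e-15)
  # first and last five injections are QCs
  expect_true(all(qc$design$is_qc[c(1:5, 116:120)]))
})

test_that("a single study sample pools to itself", {
  tab <- tiny_table(n_samples = 1)
  des <- study_design(data.frame(sample_id = "S1", subject = "A",
                                 phase = "placebo", week = 1, day = 1,
                                 injection_order = 1, is_qc = FALSE))
  qc <- make_qc_series(tab, des, qc_every = 10, n_lead = 2, n_tail = 2)
  qrows <- qc$table$intensities[qc$design$is_qc, ]
  expect_equal(unname(qrows),
               matrix(tab$intensities[1, ], 4, 3, byrow = TRUE))
  expect_error(make_qc_series(tab, des, qc_every = 0), "qc_every")
})

test_that("drift is the stated linear multiplier and is invertible", {
  g <- generate_crossover(synthetic_spec(n_features = 6))
  same <- apply_drift(g$table, g$design, 0)
  expect_identical(same$intensities, g$table$intensities)

  drifted <- apply_drift(g$table, g$design, 0.01)
  s11 <- g$design$sample_id[g$design$injection_order == 11]
  expect_equal(drifted$intensities[s11, ],
               g$table$intensities[s11, ] * 1.10, tolerance = 1e-12)

  ord <- g$design$injection_order[match(g$table$sample_ids,
                                        g$design$sample_id)]
  undone <- drifted$intensities / (1 + 0.01 * (ord - 1))
  expect_equal(undone, g$table$intensities, tolerance = 1e-10)

  expect_error(apply_drift(g$table, g$design, -0.01), "multiplier")
})

test_that("missingness injection hits the target rate and mechanism", {
  g <- generate_crossover(synthetic_spec(n_features = 80, seed = 2))
  expect_identical(inject_missing(g$table, 0)$intensities,
                   g$table$intensities)

  # 126 x 80 = 10,080 cells; binomial 99% interval around 10%
  m <- inject_missing(g$table, 0.1, "mcar", seed = 4)
  n_miss <- sum(is.na(m$intensities))
  expect_gt(n_miss, 900 * 1.008)
  expect_lt(n_miss, 1100 * 1.008)

  low <- inject_missing(g$table, 0.1, "low_intensity", seed = 4)
  cens <- is.na(low$intensities)
  expect_lt(median(g$table$intensities[cens]),
            median(g$table$intensities[!cens]))

  expect_error(inject_missing(g$table, 1), "rate")
})

test_that("reset profile controls day dependence of the active-arm shift", {
  flat <- generate_crossover(synthetic_spec(
    n_features = 10, n_affected = 10, effect_size = 1,
    reset_profile = rep(1, 5), sigma_error = 0, seed = 9))
  tr <- flat$truth$treatment[flat$design$phase == "oleuropein", ]
  expect_true(all(tr == 1))

  dec <- generate_crossover(synthetic_spec(
    n_features = 10, n_affected = 10, effect_size = 1,
    reset_profile = c(1, 0.8, 0.5, 0.2, 0), sigma_error = 0, seed = 9))
  d5 <- dec$design$phase == "oleuropein" & dec$design$day == 5
  # day-5 treated samples carry zero treatment component: expected means
  # equal placebo ("metabolome reset")
  expect_true(all(dec$truth$treatment[d5, ] == 0))
  d1 <- dec$design$phase == "oleuropein" & dec$design$day == 1
  expect_true(all(dec$truth$treatment[d1, ] == 1))
})
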