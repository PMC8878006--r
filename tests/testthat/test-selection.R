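test_that("top-loading selection is component-major and magnitude-ordered", {
  set.seed(81)
  X <- matrix(rnorm(60 * 40), 60, 40)
  X[31:60, 1:8] <- X[31:60, 1:8] + 3
  colnames(X) <- paste0("F", 1:40)
  y <- factor(rep(c("A", "B"), each = 30))
  m <- splsda_fit(X, y, n_components = 2, keepx = c(15, 15))

  sel <- select_top_loadings(m, k_per_component = 10)
  expect_lte(nrow(sel), 20)
  expect_identical(sel$rank, seq_len(nrow(sel)))
  # independent sort oracle on the dense loading table
  for (h in 1:2) {
    w <- m$x_weights[, h]
    w[sel$feature_id[sel$component < h]] <- 0  # earlier components take precedence
    want <- names(sort(abs(w[w != 0]), decreasing = TRUE))[1:10]
    expect_identical(sel$feature_id[sel$component == h], want)
  }
  # |loading| descending within component
  for (h in unique(sel$component)) {
    l <- abs(sel$loading[sel$component == h])
    expect_true(all(diff(l) <= 1e-12))
  }

  mk <- splsda_fit(X, y, n_components = 1, keepx = 3)
  expect_warning(sel3 <- select_top_loadings(mk, 10), "3 nonzero")
  expect_identical(nrow(sel3), 3L)
})

test_that("k = 1 takes the largest absolute loading", {
  set.seed(82)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- factor(rep(c("A", "B"), each = 15))
  m <- splsda_fit(X, y, n_components = 1, keepx = 3)
  m$x_weights[, 1] <- c(0.9, -0.95, 0)  # fixed loading pattern
  rownames(m$x_weights) <- paste0("F", 1:3)
  sel <- select_top_loadings(m, 1)
  expect_identical(sel$feature_id[1], "F2")
})

test_that("radius selection equals brute-force norm filtering", {
  set.seed(83)
  X <- matrix(rnorm(50 * 30), 50, 30)
  X[26:50, 1:5] <- X[26:50, 1:5] + 4
  colnames(X) <- paste0("F", 1:30)
  y <- factor(rep(c("A", "B"), each = 25))
  m <- splsda_fit(X, y, n_components = 2, keepx = c(30, 30))

  sel <- select_by_radius(m, X, start = 0.9, step = 0.1, floor = 0.5,
                          target_count = 5)
  c1 <- cor(X, m$x_scores[, 1]); c2 <- cor(X, m$x_scores[, 2])
  norm <- sqrt(c1^2 + c2^2)
  r <- attr(sel, "radius_used")
  expect_setequal(sel$feature_id, colnames(X)[norm >= r & norm <= 1 + 1e-12])

  # a feature proportional to component 1 sits on the unit circle
  X2 <- cbind(X, F31 = m$x_scores[, 1])
  m2 <- splsda_fit(X2, y, n_components = 2, keepx = c(31, 31))
  s2 <- select_by_radius(m2, X2, start = 0.9, step = 0.1, floor = 0.9)
  expect_true("F31" %in% s2$feature_id)

  # all norms below the floor: empty selection, not an error
  set.seed(84)
  Xn <- matrix(rnorm(200 * 40), 200, 40)
  colnames(Xn) <- paste0("N", 1:40)
  yn <- factor(rep(c("A", "B"), each = 100))
  mn <- splsda_fit(Xn, yn, n_components = 2, keepx = c(40, 40))
  sn <- select_by_radius(mn, Xn, start = 0.9, step = 0.1, floor = 0.88,
                         target_count = NULL)
  expect_identical(nrow(sn), 0L)

  m1 <- splsda_fit(X, y, n_components = 1, keepx = 30)
  expect_error(select_by_radius(m1, X), "2 components")
})

test_that("BH step-up matches the hand-computed example", {
  g <- generate_crossover(synthetic_spec(n_features = 4, n_affected = 0,
                                         missing_rate = 0, seed = 85))
  res <- paired_tests_fdr(g$table, g$design)
  # q-values monotone non-decreasing in sorted-p order
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-15))
  # the BH arithmetic itself, on the canonical 4-p example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(p.adjust(rep(1, 5), "BH"), rep(1, 5))
})

test_that("null simulation keeps the FDR near its nominal level", {
  fracs <- sapply(1:10, function(s) {
    g <- generate_crossover(synthetic_spec(n_features = 200, n_affected = 0,
                                           missing_rate = 0, seed = 100 + s))
    res <- paired_tests_fdr(g$table, g$design)
    mean(res$q_value < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(fracs), 0.05)
})

test_that("fold changes follow the subject-ratio convention", {
  # O = 2 x P exactly: fold change 2 +/- 0, trend up
  # subject offsets cancel within subject; week/day offsets differ between
  # a subject's two arms, so they must be zero for an exact ratio
  spec <- synthetic_spec(n_features = 6, n_affected = 6,
                         effect_size = log(2), reset_profile = rep(1, 5),
                         sigma_between = 0.5, sigma_week = 0,
                         sigma_day = 0, sigma_error = 0,
                         missing_rate = 0, seed = 86)
  g <- generate_crossover(spec)
  fc <- fold_changes(g$table, g$design)
  expect_equal(fc$fold_change, rep(2, 6), tolerance = 1e-9)
  expect_equal(fc$sd, rep(0, 6), tolerance = 1e-9)
  expect_true(all(fc$trend == "up"))

  # O = P: tie resolved down and flagged
  spec0 <- synthetic_spec(n_features = 3, n_affected = 0, effect_size = 0,
                          sigma_between = 0.3, sigma_week = 0, sigma_day = 0,
                          sigma_error = 0, missing_rate = 0, seed = 87)
  g0 <- generate_crossover(spec0)
  fc0 <- fold_changes(g0$table, g0$design)
  expect_true(all(fc0$fold_change == 1))
  expect_true(all(fc0$trend == "down"))
  expect_true(all(fc0$tie))

  # downregulated features print the reciprocal (>= 1) with trend down
  specd <- synthetic_spec(n_features = 4, n_affected = 4,
                          effect_size = -log(2), reset_profile = rep(1, 5),
                          sigma_between = 0.5, sigma_error = 0,
                          sigma_week = 0, sigma_day = 0,
                          missing_rate = 0, seed = 88)
  gd <- generate_crossover(specd)
  fcd <- fold_changes(gd$table, gd$design)
  expect_equal(fcd$fold_change, rep(2, 4), tolerance = 1e-9)
  expect_true(all(fcd$trend == "down"))
})

test_that("both selection strategies jointly recover planted features", {
  hits <- sapply(1:10, function(s) {
    spec <- synthetic_spec(n_features = 200, n_affected = 15,
                           effect_size = 1, sigma_between = 1,
                           sigma_week = 0.2, sigma_day = 0.1,
                           sigma_error = 0.3, reset_profile = rep(1, 5),
                           missing_rate = 0, seed = 200 + s)
    g <- generate_crossover(spec)
    pa <- prep_admin_matrix(g)
    Xml <- remove_variation(pa$X, pa$design$subject)$residual
    m <- splsda_fit(Xml, pa$labels, n_components = 2, keepx = c(15, 15))
    s1 <- select_top_loadings(m, 10)$feature_id
    s2 <- select_by_radius(m, Xml, start = 0.9, step = 0.1, floor = 0.5,
                           target_count = 15)$feature_id
    mean(g$truth$affected_feature_ids %in% union(s1, s2))
  })
  expect_gte(median(hits), 0.9)
})
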