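#' Candidate selection: top loadings per component
#'
#' The first strategy for extracting candidate metabolites from a fitted
#' model: per component in order, the `k` nonzero weights of largest
#' absolute value are appended (features already taken by an earlier
#' component are skipped), stopping when all sparse components have been
#' consumed.
#'
#' @param model a fitted `splsda` model.
#' @param k_per_component features taken per component (default 10).
#' @return data frame `feature_id`, `component`, `loading`, `rank`
#'   (component-major, |loading| descending within component).
#' @export
select_top_loadings <- function(model, k_per_component = 10) {
  W <- model$x_weights
  taken <- character(0)
  out <- list()
  for (h in seq_len(ncol(W))) {
    nz <- which(W[, h] != 0 & !(rownames(W) %in% taken))
    if (!length(nz)) next
    if (k_per_component > length(nz))
      warning("component ", h, ": only ", length(nz),
              " nonzero loadings available")
    ord <- nz[order(-abs(W[nz, h]), nz)]
    sel <- utils::head(ord, k_per_component)
    out[[h]] <- data.frame(feature_id = rownames(W)[sel], component = h,
                           loading = unname(W[sel, h]),
                           stringsAsFactors = FALSE)
    taken <- c(taken, rownames(W)[sel])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(feature_id = character(0), component = integer(0),
                      loading = numeric(0), rank = integer(0)))
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Candidate selection: adjustable-radius correlation circle
#'
#' The second strategy: each feature is placed on the variable
#' (correlation-circle) plot at its Pearson correlations with the first
#' two component scores. Starting from radius `start`, features whose
#' coordinate norm lies between the radius and the unit circle (the outer
#' boundary) are selected; the radius is decreased by `step` until
#' `target_count` features are selected or `floor` is passed.
#'
#' @param model a fitted `splsda` model with >= 2 components.
#' @param X the data matrix the model was fitted on (feature columns are
#'   correlated with the scores). Defaults to reconstructing correlations
#'   from the stored scores requires the matrix, so X must be supplied.
#' @param start,step,floor radius schedule (defaults 0.9, 0.1, 0.5).
#' @param target_count stop once at least this many features selected
#'   (`NULL`: single pass at `start`).
#' @return data frame `feature_id`, `cor1`, `cor2`, `radius` (norm), and
#'   attribute `radius_used`.
#' @export
select_by_radius <- function(model, X, start = 0.9, step = 0.1,
                             floor = 0.5, target_count = NULL) {
  if (model$n_components < 2) stop("need >= 2 components for the variable plot")
  if (!(step > 0 && step < start && start <= 1 && floor > 0 && floor <= start))
    stop("invalid radius schedule")
  X <- as.matrix(X)
  c1 <- suppressWarnings(stats::cor(X, model$x_scores[, 1]))[, 1]
  c2 <- suppressWarnings(stats::cor(X, model$x_scores[, 2]))[, 1]
  c1[is.na(c1)] <- 0; c2[is.na(c2)] <- 0
  norm <- sqrt(c1^2 + c2^2)
  r <- start
  repeat {
    sel <- which(norm >= r & norm <= 1 + 1e-12)
    if (is.null(target_count) || length(sel) >= target_count) break
    r <- r - step
    if (r < floor - 1e-12) break
  }
  sel <- which(norm >= max(r, floor - 1e-12) & norm <= 1 + 1e-12)
  out <- data.frame(feature_id = colnames(X)[sel], cor1 = c1[sel],
                    cor2 = c2[sel], radius = norm[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$radius), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "radius_used") <- max(r, floor)
  out
}

#' Subject-paired tests with Benjamini-Hochberg FDR correction
#'
#' Per feature, each subject's log intensities are averaged over the
#' administration days of each arm, giving one placebo and one active
#' value per subject; a two-sided paired t-test compares the arms, and
#' q-values are Benjamini-Hochberg step-up adjusted across the tested
#' feature set. Subjects missing one arm are dropped (warning); features
#' with fewer than 3 complete pairs are flagged untestable (`NA`).
#'
#' @param table a `feature_table` on the raw intensity scale.
#' @param design matching `study_design`.
#' @param features feature ids to test (default: all).
#' @return data frame `feature_id`, `p_value`, `q_value`, `n_pairs`.
#' @export
paired_tests_fdr <- function(table, design, features = table$feature_ids) {
  pm <- .subject_arm_means(table, design, features, log_scale = TRUE)
  pv <- vapply(features, function(f) {
    o <- pm$O[, f]; p <- pm$P[, f]
    ok <- stats::complete.cases(o, p)
    if (sum(ok) < 3) return(NA_real_)
    d <- o[ok] - p[ok]
    if (stats::sd(d) == 0) return(if (all(d == 0)) 1 else 0)
    stats::t.test(o[ok], p[ok], paired = TRUE)$p.value
  }, numeric(1))
  qv <- rep(NA_real_, length(pv))
  qv[!is.na(pv)] <- stats::p.adjust(pv[!is.na(pv)], method = "BH")
  npairs <- vapply(features, function(f)
    sum(stats::complete.cases(pm$O[, f], pm$P[, f])), integer(1))
  data.frame(feature_id = features, p_value = unname(pv),
             q_value = unname(qv), n_pairs = unname(npairs),
             stringsAsFactors = FALSE)
}

# per-subject arm means over administration days; rows subjects, cols features
.subject_arm_means <- function(table, design, features, log_scale = FALSE) {
  d <- design[!design$is_qc & design$phase %in% c("placebo", "oleuropein"), ,
              drop = FALSE]
  X <- table$intensities[d$sample_id, features, drop = FALSE]
  if (log_scale) X <- log(X)
  subjects <- sort(unique(d$subject))
  arm <- function(ph) {
    t(vapply(subjects, function(s) {
      idx <- d$subject == s & d$phase == ph
      if (!any(idx)) return(rep(NA_real_, length(features)))
      colMeans(X[idx, , drop = FALSE], na.rm = TRUE)
    }, numeric(length(features))))
  }
  O <- arm("oleuropein"); P <- arm("placebo")
  dimnames(O) <- dimnames(P) <- list(subjects, features)
  miss <- subjects[rowSums(is.na(O)) == length(features) |
                   rowSums(is.na(P)) == length(features)]
  if (length(miss))
    warning("subject(s) missing one arm dropped: ", paste(miss, collapse = ", "))
  list(O = O, P = P)
}

#' Fold changes between treatment arms
#'
#' Per subject, the ratio of the mean active-arm (O) intensity to the mean
#' placebo (P) intensity on the raw scale; reported as mean and SD over
#' subjects. A feature is upregulated when the mean O/P ratio exceeds 1.
#' Downregulated features are reported as the reciprocal (mean subject
#' P/O ratio), so every printed fold change is >= 1 and the trend arrow
#' carries the direction. An exact tie is reported as trend `"down"` and
#' flagged.
#'
#' @param table a `feature_table` on the raw intensity scale.
#' @param design matching `study_design`.
#' @param features feature ids (default: all).
#' @return data frame `feature_id`, `fold_change`, `sd`, `trend`
#'   (`"up"`/`"down"`), `tie` flag.
#' @export
fold_changes <- function(table, design, features = table$feature_ids) {
  pm <- .subject_arm_means(table, design, features, log_scale = FALSE)
  res <- lapply(features, function(f) {
    o <- pm$O[, f]; p <- pm$P[, f]
    ok <- stats::complete.cases(o, p)
    if (!any(ok) || any(p[ok] == 0))
      return(data.frame(feature_id = f, fold_change = NA_real_,
                        sd = NA_real_, trend = NA_character_, tie = NA))
    ratio <- o[ok] / p[ok]
    up <- mean(ratio) > 1
    tie <- mean(ratio) == 1
    r <- if (up) ratio else p[ok] / o[ok]
    data.frame(feature_id = f, fold_change = mean(r),
               sd = stats::sd(r), trend = if (up) "up" else "down",
               tie = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble a candidate-metabolite results table
#'
#' Joins a selection (either strategy) with VIP scores, FDR-corrected
#' paired tests and fold changes into one exportable table mirroring the
#' conventional reporting columns (id, m/z, tR, trend, fold change +/- SD).
#'
#' @param selection data frame with a `feature_id` column.
#' @param model fitted model (for VIP); may be `NULL`.
#' @param table,design raw-scale data for tests and fold changes.
#' @return data frame, one row per selected feature.
#' @export
selection_report <- function(selection, model, table, design) {
  feats <- unique(selection$feature_id)
  tests <- paired_tests_fdr(table, design, feats)
  fc <- fold_changes(table, design, feats)
  meta <- table$feature_meta[match(feats, table$feature_meta$feature_id),
                             c("feature_id", "mz", "rt")]
  out <- Reduce(function(a, b) merge(a, b, by = "feature_id", sort = FALSE),
                list(meta, tests, fc))
  if (!is.null(model)) {
    vip <- splsda_vip(model)
    out$vip <- unname(vip[out$feature_id])
  }
  out[match(feats, out$feature_id), , drop = FALSE]
}
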