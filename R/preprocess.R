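#' Construct a peak list
#'
#' @param mz,rt numeric vectors (Th, minutes); `intensity` optional.
#' @param intensity optional numeric vector.
#' @return a `peak_list` data frame.
#' @export
peak_list <- function(mz, rt, intensity = NULL) {
  stopifnot(length(mz) == length(rt), all(mz > 0), all(rt >= 0))
  pl <- data.frame(mz = mz, rt = rt)
  if (!is.null(intensity)) pl$intensity <- intensity
  class(pl) <- c("peak_list", class(pl))
  pl
}

#' Load a two-column (mz, rt) peak list from CSV
#' @param path CSV with `mz` and `rt` columns (optionally `intensity`).
#' @return a `peak_list`.
#' @export
load_peak_list <- function(path) {
  d <- utils::read.csv(path)
  peak_list(d$mz, d$rt, d$intensity)
}

#' Consensus matching of two peak-picker feature lists
#'
#' Greedy one-to-one matching of entries within `ppm_tol` in m/z (relative)
#' and `rt_tol` in retention time, closest pair first. Distance is the
#' normalised Euclidean combination of the ppm and rt deviations; ties are
#' broken by smaller ppm deviation, then smaller indices, so matching is
#' deterministic. This is the arithmetic behind the Venn diagram of common
#' and picker-unique features.
#'
#' @param a,b `peak_list`s (or data frames with `mz`, `rt`).
#' @param ppm_tol m/z tolerance in ppm (> 0).
#' @param rt_tol retention-time tolerance in minutes (> 0).
#' @return a `consensus_result` list: `n_common`, `n_unique_a`,
#'   `n_unique_b`, `merged` peak list (matched pairs averaged), `pairs`
#'   data frame of matched index pairs.
#' @export
consensus_features <- function(a, b, ppm_tol, rt_tol) {
  stopifnot(ppm_tol > 0, rt_tol > 0)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 && nb == 0) {
    return(structure(list(n_common = 0L, n_unique_a = 0L, n_unique_b = 0L,
                          merged = peak_list(numeric(0), numeric(0)),
                          pairs = data.frame(i = integer(0), j = integer(0))),
                     class = "consensus_result"))
  }
  cand <- NULL
  if (na > 0 && nb > 0) {
    ij <- expand.grid(i = seq_len(na), j = seq_len(nb))
    dppm <- abs(a$mz[ij$i] - b$mz[ij$j]) / a$mz[ij$i] * 1e6
    drt <- abs(a$rt[ij$i] - b$rt[ij$j])
    ok <- dppm <= ppm_tol & drt <= rt_tol
    cand <- data.frame(i = ij$i[ok], j = ij$j[ok],
                       dppm = dppm[ok], drt = drt[ok])
    cand$dist <- sqrt((cand$dppm / ppm_tol)^2 + (cand$drt / rt_tol)^2)
    cand <- cand[order(cand$dist, cand$dppm, cand$i, cand$j), , drop = FALSE]
  }
  used_a <- logical(na); used_b <- logical(nb)
  pairs <- list()
  if (!is.null(cand)) {
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(i = i, j = j)
      }
    }
  }
  pairs <- if (length(pairs)) as.data.frame(do.call(rbind, pairs))
           else data.frame(i = integer(0), j = integer(0))
  merged_mz <- c((a$mz[pairs$i] + b$mz[pairs$j]) / 2,
                 a$mz[!used_a], b$mz[!used_b])
  merged_rt <- c((a$rt[pairs$i] + b$rt[pairs$j]) / 2,
                 a$rt[!used_a], b$rt[!used_b])
  structure(list(n_common = nrow(pairs),
                 n_unique_a = sum(!used_a),
                 n_unique_b = sum(!used_b),
                 merged = peak_list(merged_mz, merged_rt),
                 pairs = pairs),
            class = "consensus_result")
}

#' Summarise a consensus result as percentages
#'
#' Each category count divided by the merged total, reported as whole
#' percentages (rounded to the nearest integer).
#'
#' @param result a `consensus_result`, or `NULL` if counts are given.
#' @param n_common,n_unique_a,n_unique_b explicit counts (override
#'   `result`).
#' @return list `total`, `pct_common`, `pct_unique_a`, `pct_unique_b`.
#' @export
summarize_consensus <- function(result = NULL, n_common = result$n_common,
                                n_unique_a = result$n_unique_a,
                                n_unique_b = result$n_unique_b) {
  counts <- c(n_common, n_unique_a, n_unique_b)
  total <- sum(counts)
  if (total == 0) stop("empty consensus result")
  pct <- round(100 * counts / total)
  list(total = total, pct_common = pct[1],
       pct_unique_a = pct[2], pct_unique_b = pct[3])
}

#' Impute missing values by probabilistic PCA
#'
#' Expectation-maximisation fit of a rank-`n_components` principal-component
#' model to the observed cells (zero-noise EM limit): the matrix is centred
#' on feature means of observed values, missing cells are initialised at 0
#' (the feature mean) and iteratively replaced by their expectation under
#' the current truncated-SVD reconstruction until the relative change of
#' the reconstruction falls below `tol`. Observed cells are never altered.
#'
#' @param table a `feature_table` (or numeric matrix).
#' @param n_components rank of the latent model; must be smaller than both
#'   dimensions.
#' @param max_iter,tol EM stopping rule.
#' @param seed kept for interface stability; the fit is deterministic.
#' @return imputed `feature_table` (or matrix, matching the input).
#' @export
impute_ppca <- function(table, n_components = 3, max_iter = 500,
                        tol = 1e-8, seed = 1L) {
  is_ft <- inherits(table, "feature_table")
  X <- if (is_ft) table$intensities else as.matrix(table)
  if (n_components >= min(dim(X)))
    stop("n_components must be < min(n_samples, n_features)")
  miss <- is.na(X)
  if (!any(miss)) return(table)
  all_miss <- colSums(!miss) == 0
  if (any(all_miss))
    stop("feature(s) with no observed value: ",
         paste(colnames(X)[all_miss], collapse = ", "))
  mu <- colMeans(X, na.rm = TRUE)
  Xfull <- X
  Xfull[miss] <- matrix(mu, nrow(X), ncol(X), byrow = TRUE)[miss]
  prev <- Xfull
  for (it in seq_len(max_iter)) {
    mu <- colMeans(Xfull)  # means re-estimated from the completed matrix
    Xc <- sweep(Xfull, 2, mu)
    sv <- svd(Xc, nu = n_components, nv = n_components)
    recon <- sv$u %*% (sv$d[seq_len(n_components)] * t(sv$v))
    Xfull[miss] <- sweep(recon, 2, mu, "+")[miss]
    delta <- sqrt(sum((Xfull - prev)^2)) /
      max(sqrt(sum(prev^2)), .Machine$double.eps)
    if (delta < tol) break
    prev <- Xfull
  }
  out <- Xfull
  out[!miss] <- X[!miss]
  if (is_ft) feature_table(out, table$feature_meta, validate = FALSE) else out
}

#' Probabilistic quotient normalisation against a pseudo-reference
#'
#' The pseudo-reference spectrum is the feature-wise mean of the reference
#' (control-group) samples. Each sample's dilution quotient is the median
#' over features of intensity / reference; the sample is divided by it.
#' Features with a zero reference value are excluded from the quotient
#' (with a warning). The quotient computation is iterated to its fixed
#' point (anchored so the reference samples' geometric-mean quotient is 1),
#' which makes the operation exactly idempotent; the first iteration is
#' classical single-pass PQN.
#'
#' @param table a `feature_table`, complete (post-imputation).
#' @param reference_sample_ids sample ids forming the control group.
#' @return normalised `feature_table`.
#' @export
normalize_reference <- function(table, reference_sample_ids) {
  X <- table$intensities
  ref_idx <- match(reference_sample_ids, rownames(X))
  if (anyNA(ref_idx)) stop("unknown reference sample id(s)")
  warned <- FALSE
  for (it in 1:200) {
    ref <- colMeans(X[ref_idx, , drop = FALSE], na.rm = TRUE)
    if (all(ref == 0)) stop("all-zero pseudo-reference")
    use <- ref > 0
    if (any(!use) && !warned) {
      warning(sum(!use), " feature(s) with zero reference value excluded",
              " from quotient")
      warned <- TRUE
    }
    q <- apply(X[, use, drop = FALSE], 1,
               function(x) stats::median(x / ref[use], na.rm = TRUE))
    q <- q / exp(mean(log(q[ref_idx])))
    if (max(abs(q - 1)) < 1e-13) break
    X <- X / q
  }
  feature_table(X, table$feature_meta, validate = FALSE)
}

#' QC-based locally weighted signal-drift correction (QC-RLSC)
#'
#' Per feature, a robust locally weighted (tricube) linear regression is
#' fitted to the pooled-QC intensities against injection order, evaluated
#' at every injection by linear interpolation between QC points (constant
#' extrapolation beyond them). Each intensity is divided by
#' `fitted / median(fitted at QCs)`, so within-run drift is removed while
#' the intensity scale is preserved.
#'
#' @param table a `feature_table` containing QC injections.
#' @param design matching `study_design` (`is_qc`, `injection_order`).
#' @param span lowess span (fraction of QC points in each local fit).
#' @return corrected `feature_table`; features whose fitted drift curve is
#'   non-positive anywhere are left uncorrected with a warning.
#' @export
qc_rlsc <- function(table, design, span = 0.75) {
  d <- design[match(table$sample_ids, design$sample_id), , drop = FALSE]
  if (anyNA(d$injection_order)) stop("injection orders missing")
  if (sum(d$is_qc) < 4) stop("need at least 4 QC injections")
  X <- table$intensities
  ord <- d$injection_order
  qc <- which(d$is_qc)
  skipped <- character(0)
  for (j in seq_len(ncol(X))) {
    qobs <- qc[!is.na(X[qc, j])]
    if (length(qobs) < 4) { skipped <- c(skipped, colnames(X)[j]); next }
    o <- order(ord[qobs])
    fit <- stats::lowess(ord[qobs][o], X[qobs, j][o], f = span)
    curve <- stats::approx(fit$x, fit$y, xout = ord, rule = 2)$y
    if (any(curve <= 0)) { skipped <- c(skipped, colnames(X)[j]); next }
    X[, j] <- X[, j] / (curve / stats::median(fit$y))
  }
  if (length(skipped))
    warning("feature(s) left uncorrected (insufficient or non-positive QC fit): ",
            paste(skipped, collapse = ", "))
  feature_table(X, table$feature_meta, validate = FALSE)
}

#' Transform and scale a feature table for multivariate modelling
#'
#' Optional elementwise `log10`, then feature-wise centring plus the chosen
#' scaling: `unit_variance` (autoscaling, SD 1), `pareto` (divide by the
#' square root of the SD) or `none` (centring only).
#'
#' @param table a `feature_table`.
#' @param transform `"none"` or `"log10"`.
#' @param scaling `"none"`, `"unit_variance"` or `"pareto"`.
#' @return a `feature_table` whose matrix is centred (and scaled); no
#'   non-negativity is implied downstream of this step.
#' @export
transform_scale <- function(table, transform = c("log10", "none"),
                            scaling = c("unit_variance", "pareto", "none")) {
  transform <- match.arg(transform)
  scaling <- match.arg(scaling)
  X <- table$intensities
  if (transform == "log10") {
    bad <- which(X <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("log10 of non-positive intensity at sample '%s', feature '%s'%s",
                   rownames(X)[bad[1, 1]], colnames(X)[bad[1, 2]],
                   if (nrow(bad) > 1) sprintf(" (and %d more cells)", nrow(bad) - 1) else ""))
    X <- log10(X)
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  if (scaling != "none") {
    s <- apply(X, 2, stats::sd, na.rm = TRUE)
    s[s == 0] <- 1
    div <- if (scaling == "unit_variance") s else sqrt(s)
    X <- sweep(X, 2, div, "/")
  }
  attr(X, "scaled:center") <- NULL
  feature_table(X, table$feature_meta, validate = FALSE)
}
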