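#' Remove one variance component by group-mean centring
#'
#' Splits a data matrix into the part explained by a grouping (its
#' between-group component) and the residual, keeping the grand mean in
#' the residual so the intensity scale survives for downstream
#' fold-change reporting:
#' `residual = X - group_mean + grand_mean`, `removed = group_mean -
#' grand_mean`. For a subject grouping this is the classical multilevel
#' within-subject split of paired omics data; the same operator removes
#' week- or day-based variation.
#'
#' @param X numeric matrix, samples in rows.
#' @param grouping vector/factor of length `nrow(X)` assigning each row to
#'   a level.
#' @return a `decomposition_result` list: `residual`, `removed`,
#'   `ss_between_groups`, `ss_residual`, `ss_total` (sums of squares about
#'   the grand mean; the first two add to the third).
#' @export
remove_variation <- function(X, grouping) {
  X <- as.matrix(X)
  if (length(grouping) != nrow(X))
    stop("grouping length (", length(grouping),
         ") does not match rows of X (", nrow(X), ")")
  g <- factor(grouping)
  grand <- colMeans(X)
  gmeans <- apply(X, 2, function(col) tapply(col, g, mean))
  if (nlevels(g) == 1) gmeans <- matrix(gmeans, nrow = 1)
  Gm <- gmeans[as.integer(g), , drop = FALSE]
  residual <- X - Gm + matrix(grand, nrow(X), ncol(X), byrow = TRUE)
  removed <- Gm - matrix(grand, nrow(X), ncol(X), byrow = TRUE)
  dimnames(residual) <- dimnames(X)
  dimnames(removed) <- dimnames(X)
  structure(list(
    residual = residual,
    removed = removed,
    ss_between_groups = sum(removed^2),
    ss_residual = sum((X - Gm)^2),
    ss_total = sum(sweep(X, 2, grand)^2)),
    class = "decomposition_result")
}

#' Build class labels from crossover design factors
#'
#' One factor gives its levels as labels; two factors give their
#' interaction (the two-level encoding, e.g. treatment x day). Unless
#' `include_baseline = TRUE` (or the only factor is `subject`), samples
#' are restricted to administration days with phase placebo/oleuropein —
#' treatment contrasts are not defined on baseline days.
#'
#' @param design a `study_design`.
#' @param factors character vector of 1 or 2 of
#'   `"phase"`, `"week"`, `"day"`, `"subject"`.
#' @param include_baseline keep baseline-phase samples.
#' @param days optional subset of administration days (e.g. `c(1, 5)` for
#'   the first-vs-last-day contrast).
#' @return named factor of class labels; names are sample ids.
#' @export
encode_classes <- function(design, factors, include_baseline = FALSE,
                           days = NULL) {
  ok <- c("phase", "week", "day", "subject")
  if (length(factors) < 1 || length(factors) > 2 || !all(factors %in% ok))
    stop("factors must be 1 or 2 of: ", paste(ok, collapse = ", "))
  d <- design[!design$is_qc, , drop = FALSE]
  if (identical(factors, "subject")) include_baseline <- TRUE
  if (!include_baseline)
    d <- d[d$phase %in% c("placebo", "oleuropein"), , drop = FALSE]
  if (!is.null(days)) d <- d[d$day %in% days, , drop = FALSE]
  if ("phase" %in% factors && !any(d$phase %in% c("placebo", "oleuropein")))
    stop("phase labels requested but no placebo/oleuropein samples present")
  if (nrow(d) == 0) stop("no samples left after restriction")
  labs <- lapply(factors, function(f) d[[f]])
  lab <- if (length(labs) == 1) factor(labs[[1]])
         else interaction(labs[[1]], labs[[2]], sep = ".", drop = TRUE)
  stats::setNames(lab, d$sample_id)
}

#' Multilevel sparse PLS-DA on a crossover feature table
#'
#' Removes one variance component (between-subject, week- or day-based)
#' by [remove_variation()] and fits a sparse PLS-DA on the residual
#' against the labels of one discriminant factor (one-level) or the
#' interaction of two (two-level). The classic configuration subtracts
#' the between-subject variation and discriminates placebo vs active arm;
#' subtracting it while keeping treatment x day exposes day-dependent
#' treatment geometry such as the metabolome reset.
#'
#' @param table a preprocessed `feature_table` (centred/scaled matrix).
#' @param design matching `study_design`.
#' @param discriminant 1 or 2 factors for [encode_classes()].
#' @param subtract factor to remove: `"subject"`, `"week"` or `"day"`,
#'   or a custom per-sample grouping vector named by sample id.
#' @param n_components,keepx passed to [splsda_fit()].
#' @param nested centre the subtracted factor within subject
#'   (grouping = subject x factor) instead of marginally.
#' @param days optional administration-day subset.
#' @param include_baseline passed to [encode_classes()].
#' @return an object of classes `mlsplsda`/`splsda` with extra fields
#'   `subtracted`, `discriminant`, `decomposition` (sums of squares).
#' @export
fit_mlsplsda <- function(table, design, discriminant, subtract,
                         n_components = 2, keepx = NULL, nested = FALSE,
                         days = NULL, include_baseline = FALSE) {
  if (is.character(subtract) && length(subtract) == 1 &&
      subtract %in% discriminant)
    stop("subtracted factor '", subtract,
         "' overlaps the discriminant factors")
  labels <- encode_classes(design, discriminant,
                           include_baseline = include_baseline, days = days)
  X <- table$intensities[names(labels), , drop = FALSE]
  d <- design[match(names(labels), design$sample_id), , drop = FALSE]
  if (is.character(subtract) && length(subtract) == 1) {
    if (!subtract %in% c("subject", "week", "day"))
      stop("subtract must be one of subject/week/day or a grouping vector")
    grouping <- if (nested && subtract != "subject")
      interaction(d$subject, d[[subtract]], drop = TRUE)
    else d[[subtract]]
    subtract_name <- subtract
  } else {
    grouping <- subtract[names(labels)]
    subtract_name <- "custom"
  }
  dec <- remove_variation(X, grouping)
  model <- splsda_fit(dec$residual, labels, n_components = n_components,
                      keepx = keepx)
  model$subtracted <- subtract_name
  model$discriminant <- discriminant
  model$decomposition <- dec[c("ss_between_groups", "ss_residual", "ss_total")]
  class(model) <- c("mlsplsda", class(model))
  model
}

#' Export a model summary as JSON
#'
#' Records the factors kept and subtracted, the class map, component
#' count, keepX and sparse weights (as index/value lists).
#'
#' @param model an `splsda`/`mlsplsda` model.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  w <- model$x_weights
  sparse_w <- lapply(seq_len(ncol(w)), function(h) {
    nz <- which(w[, h] != 0)
    list(feature = model$feature_names[nz] %||% nz, index = nz,
         value = unname(w[nz, h]))
  })
  out <- list(
    discriminant = model$discriminant %||% NA,
    subtracted = model$subtracted %||% NA,
    classes = levels(model$labels),
    n_components = model$n_components,
    keepx = model$keepx,
    weights = sparse_w)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
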