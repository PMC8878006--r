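#' Fit a sparse PLS-DA model
#'
#' Partial least squares against a one-hot (dummy) encoding of the class
#' labels, with a per-component cardinality constraint: inside the NIPALS
#' iteration the X weight vector is hard-thresholded to its `keepx[h]`
#' largest-magnitude entries (ties broken by smaller feature index) and
#' renormalised, iterated to convergence. X is deflated by regression on
#' its scores (regression mode); Y is not deflated. Scores are therefore
#' mutually orthogonal.
#'
#' @param X numeric matrix, samples x features (already transformed;
#'   the fit centres X and Y internally and stores the centring vectors).
#' @param labels class vector (>= 2 classes).
#' @param n_components number of latent components.
#' @param keepx integer vector, one entry per component: number of
#'   features allowed a nonzero weight. `NULL` keeps all features.
#' @param scale divide features by their SD before fitting.
#' @param tol,max_iter inner NIPALS stopping rule.
#' @return an object of class `splsda`: `x_weights` (p x H), `x_loadings`,
#'   `x_scores` (the X-variates), `y_loadings`, `coefficients` (for
#'   prediction at each component count), `class_map`, `keepx`, centring
#'   vectors, `labels`, `feature_names`.
#' @export
splsda_fit <- function(X, labels, n_components = 2, keepx = NULL,
                       scale = FALSE, tol = 1e-6, max_iter = 500) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  n <- nrow(X); p <- ncol(X); K <- nlevels(labels)
  if (is.null(keepx)) keepx <- rep(p, n_components)
  if (length(keepx) == 1) keepx <- rep(keepx, n_components)
  if (length(keepx) != n_components)
    stop("keepx must have one entry per component")
  if (any(keepx < 1)) stop("keepx entries must be >= 1")
  if (any(keepx > p)) {
    warning("keepx > n_features; clipped to ", p)
    keepx <- pmin(keepx, p)
  }
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- apply(Xc, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  C <- matrix(0, K, n_components)
  Xd <- Xc
  for (h in seq_len(n_components)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      w <- .hard_threshold(w, keepx[h])
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("degenerate weight vector in component ", h)
      w <- w / nw
      t_ <- Xd %*% w
      cvec <- crossprod(Yc, t_)[, 1] / sum(t_^2)
      u <- (Yc %*% cvec)[, 1] / sum(cvec^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
    }
    # deterministic sign: largest-|w| entry positive
    s <- sign(w[which.max(abs(w))])
    w <- w * s
    t_ <- Xd %*% w
    cvec <- crossprod(Yc, t_)[, 1] / sum(t_^2)
    pvec <- crossprod(Xd, t_)[, 1] / sum(t_^2)
    W[, h] <- w; P[, h] <- pvec; Tm[, h] <- t_; C[, h] <- cvec
    Xd <- Xd - tcrossprod(t_, pvec)
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Tm) <- rownames(X)
  rownames(C) <- levels(labels)
  colnames(W) <- colnames(P) <- colnames(Tm) <- colnames(C) <-
    paste0("comp", seq_len(n_components))
  structure(list(
    x_weights = W, x_loadings = P, x_scores = Tm, y_loadings = C,
    keepx = keepx, n_components = n_components,
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    class_map = levels(labels), labels = labels,
    feature_names = colnames(X)),
    class = "splsda")
}

.hard_threshold <- function(w, k) {
  if (k >= length(w)) return(w)
  keep <- order(-abs(w), seq_along(w))[seq_len(k)]
  out <- numeric(length(w))
  out[keep] <- w[keep]
  out
}

#' @export
print.splsda <- function(x, ...) {
  cat(sprintf("<%s> %d classes (%s), %d components, keepX = %s\n",
              class(x)[1], length(x$class_map),
              paste(x$class_map, collapse = "/"),
              x$n_components, paste(x$keepx, collapse = ",")))
  invisible(x)
}

# Scores of new samples under a fitted model (successive deflation).
.splsda_scores <- function(model, Xnew) {
  Xn <- sweep(as.matrix(Xnew), 2, model$x_center)
  Xn <- sweep(Xn, 2, model$x_scale, "/")
  H <- model$n_components
  Tn <- matrix(0, nrow(Xn), H)
  for (h in seq_len(H)) {
    Tn[, h] <- Xn %*% model$x_weights[, h]
    Xn <- Xn - tcrossprod(Tn[, h], model$x_loadings[, h])
  }
  Tn
}

#' Predict classes from a sparse PLS-DA model
#'
#' `max_dist` assigns the class with the largest predicted one-hot score;
#' `centroids_dist` assigns the nearest class centroid in the latent score
#' space (Euclidean).
#'
#' @param object a fitted `splsda` model.
#' @param Xnew matrix with the model's feature columns.
#' @param distance decision rule.
#' @param n_components number of components to use (default: all).
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.splsda <- function(object, Xnew,
                           distance = c("max_dist", "centroids_dist"),
                           n_components = object$n_components, ...) {
  distance <- match.arg(distance)
  if (ncol(Xnew) != length(object$x_center))
    stop("Xnew has ", ncol(Xnew), " features; model expects ",
         length(object$x_center))
  Tn <- .splsda_scores(object, Xnew)[, seq_len(n_components), drop = FALSE]
  if (distance == "max_dist") {
    Yhat <- Tn %*% t(object$y_loadings[, seq_len(n_components), drop = FALSE])
    Yhat <- sweep(Yhat, 2, object$y_center, "+")
    cls <- object$class_map[max.col(Yhat, ties.method = "first")]
  } else {
    Tr <- object$x_scores[, seq_len(n_components), drop = FALSE]
    cent <- apply(Tr, 2, function(col) tapply(col, object$labels, mean))
    cent <- matrix(cent, nrow = nlevels(object$labels))
    d2 <- outer(rowSums(Tn^2), rowSums(cent^2), "+") - 2 * Tn %*% t(cent)
    cls <- object$class_map[max.col(-d2, ties.method = "first")]
  }
  factor(cls, levels = object$class_map)
}

# Stratified fold assignment; guarantees every fold sees every class when
# each class has >= n_folds members, otherwise re-stratifies then errors.
.stratified_folds <- function(labels, n_folds) {
  n <- length(labels)
  for (attempt in 1:20) {
    fold <- integer(n)
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(f)
      nlevels(droplevels(labels[fold != f])) == nlevels(labels), logical(1)))
    if (ok) return(fold)
  }
  stop("cannot stratify: a class is too small for ", n_folds, " folds")
}

#' Tune the sparsity of a sparse PLS-DA by cross-validation
#'
#' Repeated stratified M-fold cross-validation over a grid of keepX
#' values (the same keepX applied to every component at a grid point).
#' Two tuning criteria are computed: the mean misclassification rate per
#' component (prediction with components 1..h), and the correlation
#' criterion — the mean Pearson correlation (absolute value, to resolve
#' component sign indeterminacy) between cross-validation-predicted
#' component scores and the full-model scores.
#'
#' @param X,labels data and classes.
#' @param keepx_grid integer vector of candidate keepX values.
#' @param n_components number of components.
#' @param n_folds folds per repeat (default 7).
#' @param n_repeats CV repeats with distinct fold seeds.
#' @param criterion which criterion picks `chosen_keepx`.
#' @param seed RNG seed.
#' @param distance prediction rule.
#' @return a `tune_result` list: `error` and `correlation` matrices
#'   (grid x component), `keepx_grid`, `chosen_keepx`.
#' @export
splsda_tune <- function(X, labels, keepx_grid = c(50, 60, 70),
                        n_components = 2, n_folds = 7, n_repeats = 10,
                        criterion = c("error", "correlation"), seed = 1L,
                        distance = "max_dist") {
  criterion <- match.arg(criterion)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (!length(keepx_grid)) stop("empty keepx_grid")
  labels <- factor(labels)
  X <- as.matrix(X)
  set.seed(seed)
  G <- length(keepx_grid)
  err <- array(0, c(G, n_components))
  corr <- array(0, c(G, n_components))
  full <- lapply(keepx_grid, function(k)
    splsda_fit(X, labels, n_components, keepx = rep(k, n_components)))
  for (r in seq_len(n_repeats)) {
    fold <- .stratified_folds(labels, n_folds)
    for (g in seq_len(G)) {
      kx <- rep(keepx_grid[g], n_components)
      Tcv <- matrix(NA_real_, nrow(X), n_components)
      wrong <- matrix(0, n_folds, n_components)
      ntest <- integer(n_folds)
      for (f in seq_len(n_folds)) {
        tr <- fold != f; te <- !tr
        m <- splsda_fit(X[tr, , drop = FALSE], labels[tr],
                        n_components, keepx = kx)
        Tn <- .splsda_scores(m, X[te, , drop = FALSE])
        Tcv[te, ] <- Tn
        ntest[f] <- sum(te)
        for (h in seq_len(n_components)) {
          pr <- predict(m, X[te, , drop = FALSE], distance = distance,
                        n_components = h)
          wrong[f, h] <- sum(pr != labels[te])
        }
      }
      err[g, ] <- err[g, ] + colSums(wrong) / sum(ntest)
      for (h in seq_len(n_components)) {
        corr[g, h] <- corr[g, h] +
          abs(stats::cor(Tcv[, h], full[[g]]$x_scores[, h]))
      }
    }
  }
  err <- err / n_repeats
  corr <- corr / n_repeats
  dimnames(err) <- dimnames(corr) <-
    list(paste0("keepx", keepx_grid), paste0("comp", seq_len(n_components)))
  chosen <- vapply(seq_len(n_components), function(h) {
    if (criterion == "error") keepx_grid[which.min(err[, h])]
    else keepx_grid[which.max(corr[, h])]
  }, numeric(1))
  structure(list(keepx_grid = keepx_grid, error = err, correlation = corr,
                 criterion = criterion, chosen_keepx = chosen),
            class = "tune_result")
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP: the weighted mean over components of the squared
#' normalised weights, weighted by the response variance explained by each
#' component (`sum(c_h^2) * sum(t_h^2)`), scaled so the mean squared VIP
#' over features is 1. Features with VIP above a threshold (conventionally
#' 1.5 here) are considered discriminating.
#'
#' @param model a fitted `splsda` model.
#' @return named numeric vector of VIP scores.
#' @export
splsda_vip <- function(model) {
  W <- model$x_weights
  ssh <- vapply(seq_len(model$n_components), function(h)
    sum(model$y_loadings[, h]^2) * sum(model$x_scores[, h]^2), numeric(1))
  if (sum(ssh) <= 0) stop("model explains no response variance")
  p <- nrow(W)
  w2 <- sweep(W^2, 2, colSums(W^2), "/")   # weights are unit norm already
  vip <- sqrt(p * as.vector(w2 %*% ssh) / sum(ssh))
  stats::setNames(vip, rownames(W))
}

#' Cross-validated performance of a sparse PLS-DA configuration
#'
#' R2 per component is the cumulative fraction of (centred one-hot)
#' response variance explained in-fit; Q2 per component is
#' `1 - PRESS/TSS` from repeated stratified M-fold cross-validation.
#' Overall and balanced (class-averaged) error rates are reported at the
#' full component count.
#'
#' @param X,labels data and classes.
#' @param n_components,keepx model settings.
#' @param n_folds,n_repeats,seed CV settings (default seven-fold).
#' @param distance prediction rule.
#' @return a `performance_result` list: `r2`, `q2` (per component),
#'   `error_rate`, `balanced_error_rate`.
#' @export
splsda_performance <- function(X, labels, n_components = 2, keepx = NULL,
                               n_folds = 7, n_repeats = 1, seed = 1L,
                               distance = "max_dist") {
  labels <- factor(labels)
  X <- as.matrix(X)
  set.seed(seed)
  full <- splsda_fit(X, labels, n_components, keepx = keepx)
  Y <- stats::model.matrix(~ labels - 1)
  Yc <- sweep(Y, 2, colMeans(Y))
  tss <- sum(Yc^2)
  r2 <- vapply(seq_len(n_components), function(h) {
    Yhat <- full$x_scores[, seq_len(h), drop = FALSE] %*%
      t(full$y_loadings[, seq_len(h), drop = FALSE])
    1 - sum((Yc - Yhat)^2) / tss
  }, numeric(1))
  press <- matrix(0, n_repeats, n_components)
  wrong <- 0; wrong_by_class <- stats::setNames(rep(0, nlevels(labels)), levels(labels))
  n_by_class <- table(labels) * n_repeats
  for (r in seq_len(n_repeats)) {
    fold <- .stratified_folds(labels, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- !tr
      m <- splsda_fit(X[tr, , drop = FALSE], labels[tr], n_components,
                      keepx = keepx)
      Tn <- .splsda_scores(m, X[te, , drop = FALSE])
      Yte <- Yc[te, , drop = FALSE]
      Ymean_tr <- colMeans(Y[tr, , drop = FALSE])
      for (h in seq_len(n_components)) {
        Yhat <- Tn[, seq_len(h), drop = FALSE] %*%
          t(m$y_loadings[, seq_len(h), drop = FALSE])
        # predicted on the centred scale of the training fold
        Yhat <- sweep(Yhat, 2, Ymean_tr - colMeans(Y), "+")
        press[r, h] <- press[r, h] + sum((Yte - Yhat)^2)
      }
      pr <- predict(m, X[te, , drop = FALSE], distance = distance)
      bad <- pr != labels[te]
      wrong <- wrong + sum(bad)
      tb <- tapply(bad, labels[te], sum)
      tb[is.na(tb)] <- 0
      wrong_by_class <- wrong_by_class + tb
    }
  }
  q2 <- 1 - colMeans(press) / tss
  structure(list(
    r2 = r2, q2 = q2,
    error_rate = wrong / (length(labels) * n_repeats),
    balanced_error_rate = mean(wrong_by_class / as.numeric(n_by_class))),
    class = "performance_result")
}
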