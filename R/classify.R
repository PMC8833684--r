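#' Fit the wrapper linear discriminant classifier
#'
#' Fits a two-class linear discriminant: the weight vector is
#' `omega = Sigma^-1 (mu1 - mu0)` with `Sigma` the pooled within-class
#' covariance, and a sample is labelled 1 exactly when `omega . x > S`. The
#' threshold `S` is set from the class means and training priors
#' (`S = omega . (mu0 + mu1)/2 - log(pi1/pi0)`), the standard posterior cut
#' for Gaussian classes with shared covariance.
#'
#' When the pooled covariance is rank-deficient or the problem is
#' under-determined (`d >= n - 2`, duplicated or collinear features), a
#' Ledoit-Wolf-style shrinkage toward a scaled identity is applied with
#' automatically estimated intensity, so fitting never fails on degenerate
#' designs. Well-conditioned problems use the exact solve, which keeps
#' predictions invariant to affine rescaling of individual features.
#'
#' The magnitude `|omega_j|` of a fitted weight is used throughout the
#' package as the relative importance of feature `j`.
#'
#' @param table A [feature_table()] (or numeric matrix with column names).
#' @param y Binary 0/1 vector with both classes present.
#' @return An object of class `lda_model` with elements `weights`,
#'   `threshold`, `feature_names`, `class_priors`, `shrinkage` (the
#'   intensity used, 0 for the exact solve).
#' @export
fit_lda <- function(table, y) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  y <- as.integer(y)
  n <- nrow(X)
  d <- ncol(X)
  if (length(y) != n) stop_efs("y length mismatch", class = "parameter_error")
  if (length(unique(y)) < 2L) {
    stop_efs("y has a single class", class = "degenerate_label_error")
  }
  i0 <- y == 0L
  i1 <- y == 1L
  n0 <- sum(i0); n1 <- sum(i1)
  mu0 <- colMeans(X[i0, , drop = FALSE])
  mu1 <- colMeans(X[i1, , drop = FALSE])
  Xc <- X
  Xc[i0, ] <- sweep(X[i0, , drop = FALSE], 2L, mu0)
  Xc[i1, ] <- sweep(X[i1, , drop = FALSE], 2L, mu1)
  n_eff <- max(n - 2L, 1L)
  S <- crossprod(Xc) / n_eff
  delta <- mu1 - mu0

  alpha <- 0
  need_shrink <- d >= n - 2L
  if (!need_shrink) {
    ok <- tryCatch({
      R <- chol(S)
      rc <- 1 / (kappa(R, exact = FALSE)^2)
      is.finite(rc) && rc > 1e-12
    }, error = function(e) FALSE)
    need_shrink <- !ok
  }
  if (need_shrink) {
    m <- mean(diag(S))
    if (m <= 0) {
      # all features constant: no discriminant direction
      w <- rep(0, d)
    } else {
      d2 <- sum((S - diag(m, d))^2)
      rs <- rowSums(Xc^2)
      xsx <- sum((Xc %*% S) * Xc)
      b2raw <- (sum(rs^2) - 2 * xsx + n_eff * sum(S^2)) / n_eff^2
      alpha <- if (d2 > 0) min(1, max(b2raw, 0) / d2) else 1
      alpha <- max(alpha, 1e-4)  # floor keeps the solve well-posed
      Ssh <- (1 - alpha) * S + diag(alpha * m, d)
      w <- drop(solve(Ssh, delta))
    }
  } else {
    w <- drop(solve(S, delta))
  }
  thr <- sum(w * (mu0 + mu1)) / 2 - log(n1 / n0)
  structure(
    list(weights = stats::setNames(w, colnames(X)), threshold = thr,
         feature_names = colnames(X),
         class_priors = c(`0` = n0 / n, `1` = n1 / n),
         shrinkage = alpha),
    class = "lda_model"
  )
}

#' Predict class labels from a fitted discriminant
#'
#' Applies the decision rule: label 1 iff `omega . x > S`.
#'
#' @param object An `lda_model` from [fit_lda()].
#' @param newdata A [feature_table()] or numeric matrix whose columns cover
#'   the model's features.
#' @param ... Unused.
#' @return Integer 0/1 vector of predicted labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$values else
    as.matrix(newdata)
  X <- X[, object$feature_names, drop = FALSE]
  as.integer(drop(X %*% object$weights) > object$threshold)
}

#' @export
print.lda_model <- function(x, ...) {
  cat("lda_model: ", length(x$weights), " features; shrinkage = ",
      signif(x$shrinkage, 3), "\n", sep = "")
  invisible(x)
}

#' Balanced accuracy
#'
#' The mean of sensitivity and specificity. Unlike raw accuracy it is 0.5
#' for any constant predictor regardless of class balance, which is what
#' makes it usable on tasks with prevalences far from one half.
#'
#' @param y_true Binary 0/1 vector containing both classes.
#' @param y_pred Binary 0/1 vector of the same length.
#' @return Scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop_efs("length mismatch", class = "parameter_error")
  }
  if (length(unique(y_true)) < 2L) {
    stop_efs("balanced accuracy undefined: y_true has one class",
      class = "undefined_metric_error")
  }
  sens <- mean(y_pred[y_true == 1L] == 1L)
  spec <- mean(y_pred[y_true == 0L] == 0L)
  (sens + spec) / 2
}

#' Cross-validation scheme
#'
#' @param k Number of folds (default 5).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param seed Integer seed controlling the fold assignment.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(k = 5L, stratified = TRUE, seed = 1L) {
  k <- assert_scalar_int(k, "k", 2L)
  structure(list(k = k, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

# Seeded (stratified) fold assignment; returns an integer vector of fold
# ids in 1..k.
make_folds <- function(y, scheme) {
  n <- length(y)
  if (scheme$k > n) stop_efs("k exceeds n", class = "parameter_error")
  with_local_seed(scheme$seed, {
    folds <- integer(n)
    if (scheme$stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep_len(seq_len(scheme$k), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(scheme$k), n))
    }
    folds
  })
}

#' Cross-validated balanced accuracy of the wrapper classifier
#'
#' Stratified seeded k-fold cross-validation of [fit_lda()]: per-fold
#' held-out balanced accuracy, its mean, and the population standard
#' deviation over folds (divide by k, so identical inputs always reproduce
#' the same numbers bit-for-bit).
#'
#' @param table A [feature_table()] or numeric matrix.
#' @param y Binary 0/1 vector.
#' @param scheme A [cv_scheme()].
#' @return List with `mean`, `sd`, `per_fold` (length-k numeric).
#' @export
cv_bacc <- function(table, y, scheme = cv_scheme()) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  y <- as.integer(y)
  folds <- make_folds(y, scheme)
  per_fold <- vapply(seq_len(scheme$k), function(f) {
    te <- folds == f
    if (length(unique(y[te])) < 2L || length(unique(y[!te])) < 2L) {
      stop_efs("fold ", f, " is missing a class",
        class = "stratification_error")
    }
    model <- fit_lda(X[!te, , drop = FALSE], y[!te])
    balanced_accuracy(y[te], predict(model, X[te, , drop = FALSE]))
  }, numeric(1))
  m <- mean(per_fold)
  list(mean = m, sd = sqrt(mean((per_fold - m)^2)), per_fold = per_fold)
}

#' Weight-magnitude feature importance
#'
#' The relative importance of a feature under the linear wrapper is the
#' magnitude of its fitted discriminant weight, `|omega_j|`; the sign of a
#' weight carries no importance information.
#'
#' @param model An `lda_model` from [fit_lda()].
#' @return Named non-negative numeric vector, one entry per feature.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "lda_model"))
  abs(model$weights)
}
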