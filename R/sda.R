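# Sparse discriminant selection via elastic-net penalised optimal scoring.
#
# For the two-class case the discriminant direction solves
#   min_beta ||y_c - X_s beta||^2 + lambda ||beta||_1 + gamma ||beta||_2^2
# with X_s the column-standardised features and y_c the centred class
# indicator. The L1 weight lambda controls how many coefficients are
# non-zero; it is tuned by bisection so that the support has exactly the
# requested size. The solve itself is delegated to glmnet's coordinate
# descent via the penalty mapping below.

# Map (lambda, gamma) in the objective above to glmnet's (lambda, alpha):
# glmnet minimises 1/(2n)||y-Xb||^2 + L[a||b||_1 + (1-a)/2 ||b||_2^2],
# so L*a = lambda/(2n) and L*(1-a) = gamma/n.
glmnet_penalty <- function(lambda, gamma, n) {
  a <- lambda / (2 * n)
  b <- gamma / n
  list(lambda = a + b, alpha = if (a + b > 0) a / (a + b) else 1)
}

#' Penalised discriminant coefficients at fixed hyperparameters
#'
#' Solves the elastic-net penalised scoring problem for a two-class label
#' at given L1 weight `lambda` and ridge weight `gamma`. With both
#' penalties zero the exact least-squares direction is returned (full-rank
#' designs).
#'
#' @param table A [feature_table()] or numeric matrix.
#' @param y Binary 0/1 labels.
#' @param lambda L1 penalty weight (>= 0).
#' @param gamma Ridge penalty weight (>= 0).
#' @return Named numeric coefficient vector (length d, on the standardised
#'   scale).
#' @export
sda_coefficients <- function(table, y, lambda, gamma) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  y <- as.integer(y)
  n <- nrow(X)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0  # constant columns drop out
  yc <- y - mean(y)
  if (lambda == 0 && gamma == 0) {
    beta <- drop(solve(crossprod(Xs), crossprod(Xs, yc)))
    return(stats::setNames(beta, colnames(X)))
  }
  pen <- glmnet_penalty(lambda, gamma, n)
  # decreasing warm-start path ending exactly at the target lambda
  lam_max <- max(abs(crossprod(Xs, yc))) / (n * max(pen$alpha, 1e-3))
  top <- max(lam_max, pen$lambda * 1.001)
  path <- exp(seq(log(top), log(pen$lambda), length.out = 25L))
  fit <- glmnet::glmnet(Xs, yc, family = "gaussian", alpha = pen$alpha,
                        lambda = path, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-11)
  beta <- drop(as.matrix(stats::coef(fit, s = pen$lambda, exact = FALSE)))[-1L]
  stats::setNames(beta, colnames(X))
}

#' Sparse discriminant feature selection (SDA)
#'
#' Selects features as the support of an elastic-net penalised discriminant
#' direction. The L1 weight is tuned by bisection on `lambda_bracket`
#' (log scale) until exactly `target_p` coefficients are non-zero; if the
#' support size jumps past `target_p` everywhere in the bracket, the
#' nearest achievable support is returned and a cardinality-miss warning is
#' recorded in `details`. A linear discriminant is then refit on the
#' selected features and its cross-validated balanced accuracy recorded.
#'
#' @param table A [feature_table()].
#' @param y Binary 0/1 labels.
#' @param target_p Desired number of non-zero coefficients.
#' @param gamma Ridge weight (default 1); larger values stabilise the
#'   support on collinear designs.
#' @param lambda_bracket Positive `(low, high)` bracket for the L1 weight;
#'   `NULL` auto-brackets from the null threshold (the smallest lambda
#'   zeroing every coefficient) down to 1e-6 times it.
#' @param tol Relative bracket width at which bisection stops.
#' @param scheme [cv_scheme()] for the post-selection accuracy.
#' @return A [selection_result()]; `details` carries `beta`, the tuned
#'   `lambda`, `cardinality_miss` and the refit accuracy.
#' @export
select_sda <- function(table, y, target_p, gamma = 1,
                       lambda_bracket = NULL, tol = 1e-4,
                       scheme = cv_scheme()) {
  d <- length(table$feature_names)
  target_p <- assert_scalar_int(target_p, "target_p")
  if (target_p > d) stop_efs("target_p exceeds d", class = "parameter_error")
  X <- table$values
  n <- nrow(X)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  yc <- as.integer(y) - mean(as.integer(y))
  if (is.null(lambda_bracket)) {
    # null threshold in objective units: lambda0 = 2 max|Xs' yc|
    lam0 <- 2 * max(abs(crossprod(Xs, yc)))
    lambda_bracket <- c(lam0 * 1e-6, lam0 * 1.01)
  }
  lo <- lambda_bracket[1L]; hi <- lambda_bracket[2L]
  if (lo <= 0 || lo >= hi) {
    stop_efs("lambda_bracket must be positive with low < high",
      class = "parameter_error")
  }
  nnz <- function(lam) {
    beta <- sda_coefficients(table, y, lam, gamma)
    list(beta = beta, k = sum(beta != 0))
  }
  best <- NULL     # exact hit
  nearest <- NULL  # closest support size seen
  note <- function(r, lam) {
    if (r$k == target_p && is.null(best)) best <<- list(beta = r$beta, lambda = lam)
    if (is.null(nearest) || abs(r$k - target_p) < abs(nearest$k - target_p)) {
      nearest <<- list(beta = r$beta, lambda = lam, k = r$k)
    }
  }
  r_lo <- nnz(lo); note(r_lo, lo)
  r_hi <- nnz(hi); note(r_hi, hi)
  if (is.null(best) && r_lo$k >= target_p && r_hi$k <= target_p) {
    while (hi / lo > 1 + tol) {
      mid <- sqrt(lo * hi)
      r <- nnz(mid); note(r, mid)
      if (!is.null(best)) break
      if (r$k > target_p) lo <- mid else hi <- mid
    }
  }
  miss <- is.null(best)
  pick <- if (miss) nearest else best
  if (miss) {
    warning("SDA cardinality miss: requested ", target_p,
            " features, achieved ", sum(pick$beta != 0), call. = FALSE)
  }
  sel <- names(pick$beta)[pick$beta != 0]
  sel <- table$feature_names[table$feature_names %in% sel]
  acc <- if (length(sel) >= 1L) {
    cv_bacc(ft_subset(table, sel), y, scheme)
  } else {
    list(mean = 0.5, sd = 0)
  }
  selection_result(sel, "SDA",
    list(target_p = target_p, gamma = gamma,
         lambda_bracket = lambda_bracket, tol = tol),
    table,
    trace = data.frame(active_features = length(sel),
                       bacc_mean = acc$mean, bacc_sd = acc$sd),
    details = list(beta = pick$beta, lambda = pick$lambda,
                   cardinality_miss = miss, cv_bacc = acc$mean))
}
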