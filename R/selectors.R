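# Eliminative selectors: every selector consumes a feature table (plus
# labels where supervised) and returns a selection_result. All randomness
# is seeded; selectors are pure functions of (data, params, seed).

#' Construct a selection result
#'
#' Common return type of all selectors: the selected feature subset, the
#' selector's name and parameters, an optional per-step trace of
#' `(active_features, bacc_mean, bacc_sd)`, and selector-specific details
#' (e.g. the penalised coefficient vector for the sparse discriminant
#' selector, or the best fitness for the genetic search).
#'
#' @param selected Character vector of selected feature names (unique,
#'   all present in the source table).
#' @param selector_name Character scalar.
#' @param params Named list of parameters used.
#' @param table The source [feature_table()] (membership check).
#' @param trace Data frame with columns `active_features`, `bacc_mean`,
#'   `bacc_sd`; may be empty.
#' @param seed Integer seed or `NULL` for deterministic selectors.
#' @param details Named list of extras.
#' @return Object of class `selection_result`.
#' @export
selection_result <- function(selected, selector_name, params, table,
                             trace = empty_trace(), seed = NULL,
                             details = list()) {
  selected <- as.character(selected)
  if (anyDuplicated(selected)) {
    stop_efs("duplicate selected features", class = "validation_error")
  }
  if (!all(selected %in% table$feature_names)) {
    stop_efs("selected features not present in table",
      class = "validation_error")
  }
  if (nrow(trace) > 1L && any(diff(trace$active_features) >= 0)) {
    stop_efs("trace feature counts must be strictly decreasing",
      class = "validation_error")
  }
  structure(
    list(selected = selected, selector_name = selector_name,
         params = params, trace = trace, seed = seed, details = details),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$selector_name, "]: ", length(x$selected),
      " features\n", sep = "")
  invisible(x)
}

empty_trace <- function() {
  data.frame(active_features = integer(), bacc_mean = numeric(),
             bacc_sd = numeric())
}

#' Random feature selection
#'
#' Uniformly samples `p` features without replacement. Despite its high
#' variance, random selection is the reference against which engineered
#' selectors must show an advantage.
#'
#' @param table A [feature_table()].
#' @param p Subset size.
#' @param seed Integer seed.
#' @return A [selection_result()].
#' @export
select_random <- function(table, p, seed = 1L) {
  d <- length(table$feature_names)
  p <- assert_scalar_int(p, "p")
  if (p > d) stop_efs("p exceeds feature count", class = "parameter_error")
  sel <- with_local_seed(seed, sample(table$feature_names, p))
  sel <- table$feature_names[table$feature_names %in% sel]
  selection_result(sel, "RND", list(p = p), table, seed = seed)
}

#' Highly-correlated-feature removal (HCFR)
#'
#' Unsupervised decorrelation: features are clustered by single-linkage
#' agglomerative clustering under the affinity
#' `1 - |pearson_corr(f_p, f_q)|`, the dendrogram is cut at distance
#' `1 - max_correlation`, and one uniformly random representative is drawn
#' per cluster. Single linkage guarantees that any two features landing in
#' different clusters have `|corr| <= max_correlation`, so the selected set
#' respects the threshold by construction. Zero-variance features have no
#' defined correlation and each form their own cluster.
#'
#' @param table A [feature_table()].
#' @param max_correlation Maximum allowed |correlation| between any two
#'   selected features, in (0, 1).
#' @param seed Integer seed for the per-cluster sampling.
#' @return A [selection_result()] whose size is data-driven (the number of
#'   clusters).
#' @export
select_hcfr <- function(table, max_correlation = 0.95, seed = 1L) {
  S <- max_correlation
  if (S <= 0 || S >= 1) {
    stop_efs("max_correlation must lie in (0, 1)", class = "parameter_error")
  }
  X <- table$values
  if (nrow(X) < 3L) stop_efs("need n >= 3", class = "parameter_error")
  sds <- apply(X, 2L, stats::sd)
  const <- sds == 0
  nms <- table$feature_names
  cluster_of <- integer(length(nms))
  if (sum(!const) >= 2L) {
    C <- stats::cor(X[, !const, drop = FALSE])
    D <- stats::as.dist(1 - abs(C))
    hc <- stats::hclust(D, method = "single")
    cl <- stats::cutree(hc, h = 1 - S)
    cluster_of[!const] <- cl
  } else if (sum(!const) == 1L) {
    cluster_of[!const] <- 1L
  }
  # constant features: one singleton cluster each
  k <- max(cluster_of, 0L)
  cluster_of[const] <- k + seq_len(sum(const))
  reps <- with_local_seed(seed, {
    vapply(split(nms, cluster_of), function(members) {
      if (length(members) == 1L) members else sample(members, 1L)
    }, character(1))
  })
  sel <- nms[nms %in% reps]
  selection_result(sel, "HCFR",
    list(max_correlation = S, n_constant = sum(const)),
    table, seed = seed,
    details = list(n_clusters = length(unique(cluster_of))))
}

# One scoring pass for RFE: returns list(importance, bacc_mean, bacc_sd).
# Without cv: resubstitution BACC and |omega| from a single fit. With cv:
# per-fold mean of |omega| (not |mean omega|, avoiding sign cancellation)
# and fold mean/sd of held-out BACC.
rfe_score <- function(X, y, cv) {
  if (is.null(cv)) {
    model <- fit_lda(X, y)
    bacc <- balanced_accuracy(y, predict(model, X))
    list(importance = feature_importance(model), bacc_mean = bacc,
         bacc_sd = 0)
  } else {
    folds <- make_folds(y, cv)
    imps <- matrix(0, cv$k, ncol(X))
    baccs <- numeric(cv$k)
    for (f in seq_len(cv$k)) {
      te <- folds == f
      if (length(unique(y[te])) < 2L || length(unique(y[!te])) < 2L) {
        stop_efs("fold ", f, " is missing a class",
          class = "stratification_error")
      }
      model <- fit_lda(X[!te, , drop = FALSE], y[!te])
      imps[f, ] <- feature_importance(model)
      baccs[f] <- balanced_accuracy(y[te], predict(model, X[te, , drop = FALSE]))
    }
    m <- mean(baccs)
    list(importance = colMeans(imps), bacc_mean = m,
         bacc_sd = sqrt(mean((baccs - m)^2)))
  }
}

#' Recursive feature elimination (RFE)
#'
#' Greedy supervised elimination: repeatedly fit the linear discriminant on
#' the active features, rank them by `|omega|`, and remove the `step_n`
#' least important (ties broken deterministically by removing the feature
#' with the larger column index) until exactly `target_p` remain. With a
#' [cv_scheme()] supplied, importances are averaged over the k folds and
#' the trace records fold mean/sd of held-out balanced accuracy per step
#' (the RFE-CV inner loop); otherwise the trace records resubstitution
#' accuracy.
#'
#' An optional anti-correlated-pair prefilter ([haff_filter()]) may be
#' applied before elimination starts.
#'
#' @param table A [feature_table()].
#' @param y Binary 0/1 labels.
#' @param target_p Number of features to retain.
#' @param step_n Features removed per step (default 1).
#' @param cv Optional [cv_scheme()].
#' @param haff Optional threshold in (0,1): apply the anti-correlated-pair
#'   prefilter at this threshold first.
#' @return A [selection_result()] with one trace row per elimination step.
#' @export
select_rfe <- function(table, y, target_p, step_n = 1L, cv = NULL,
                       haff = NULL) {
  target_p <- assert_scalar_int(target_p, "target_p")
  step_n <- assert_scalar_int(step_n, "step_n")
  tab <- table
  pre_trace <- empty_trace()
  if (!is.null(haff)) {
    hf <- haff_filter(tab, y, threshold = haff)
    tab <- ft_subset(tab, hf$selected)
    pre_trace <- hf$trace
  }
  d <- length(tab$feature_names)
  if (target_p > d) {
    stop_efs("target_p exceeds available feature count (", d, ")",
      class = "parameter_error")
  }
  active <- tab$feature_names
  idx <- match(active, table$feature_names)
  trace <- list()
  while (length(active) > target_p) {
    X <- tab$values[, active, drop = FALSE]
    sc <- tryCatch(rfe_score(X, y, cv), error = function(e) {
      stop_efs("RFE step at ", length(active), " features: ",
        conditionMessage(e), class = class(e)[1L])
    })
    trace[[length(trace) + 1L]] <- data.frame(
      active_features = length(active), bacc_mean = sc$bacc_mean,
      bacc_sd = sc$bacc_sd)
    k <- min(step_n, length(active) - target_p)
    cur_idx <- match(active, table$feature_names)
    ord <- order(sc$importance, -cur_idx)  # ties: larger index removed first
    active <- active[-ord[seq_len(k)]]
  }
  selection_result(active, if (is.null(cv)) "RFE" else "RFE-CV",
    list(target_p = target_p, step_n = step_n, haff = haff),
    table, trace = rbind(pre_trace, do.call(rbind, trace)))
}

#' RFE with cross-validated choice of the feature count
#'
#' Runs the full elimination path (one feature removed per step, k-fold
#' accuracy at every step down to a single feature) and then picks the
#' smallest feature count whose mean held-out balanced accuracy is at least
#' `best mean - trade_off_sd * sd(best step)`. The feature count is thus an
#' output of the procedure, not an input; `trade_off_sd = 0` returns the
#' count achieving the maximum mean (smallest count on ties).
#'
#' @param table A [feature_table()].
#' @param y Binary 0/1 labels.
#' @param scheme A [cv_scheme()] used at every step.
#' @param trade_off_sd Accuracy/feature-count trade-off in units of the
#'   fold sd at the best step (default 1).
#' @param haff Optional prefilter threshold, as in [select_rfe()].
#' @return A [selection_result()]; `details$chosen_p` records the count.
#' @export
select_rfe_cv_auto <- function(table, y, scheme = cv_scheme(),
                               trade_off_sd = 1, haff = NULL) {
  tab <- table
  pre_trace <- empty_trace()
  if (!is.null(haff)) {
    hf <- haff_filter(tab, y, threshold = haff)
    tab <- ft_subset(tab, hf$selected)
    pre_trace <- hf$trace
  }
  active <- tab$feature_names
  sets <- list()
  rows <- list()
  repeat {
    X <- tab$values[, active, drop = FALSE]
    sc <- rfe_score(X, y, scheme)
    rows[[length(rows) + 1L]] <- data.frame(
      active_features = length(active), bacc_mean = sc$bacc_mean,
      bacc_sd = sc$bacc_sd)
    sets[[length(sets) + 1L]] <- active
    if (length(active) == 1L) break
    cur_idx <- match(active, table$feature_names)
    ord <- order(sc$importance, -cur_idx)
    active <- active[-ord[1L]]
  }
  path <- do.call(rbind, rows)
  best <- which.max(path$bacc_mean)
  floor_bacc <- path$bacc_mean[best] - trade_off_sd * path$bacc_sd[best]
  ok <- which(path$bacc_mean >= floor_bacc)
  pick <- ok[which.min(path$active_features[ok])]
  selection_result(sets[[pick]], "RFECV",
    list(k = scheme$k, trade_off_sd = trade_off_sd, haff = haff),
    table, trace = rbind(pre_trace, path),
    details = list(chosen_p = path$active_features[pick],
                   best_mean = path$bacc_mean[best]))
}

#' Anti-correlated feature-pair prefilter (HAFF)
#'
#' Strongly anti-correlated feature pairs (`corr < -T`, `T ~ 0.95`) let a
#' linear classifier balance large opposing weights against each other,
#' which distorts the weight-magnitude importance ranking that greedy
#' eliminative selectors rely on. This filter removes them before the main
#' selector runs: at each pass it finds all pairs with Pearson correlation
#' below `-threshold`, removes from each pair the member with the smaller
#' fitted `|omega|`, refits, and repeats until no such pair remains. With
#' no anti-correlated pairs the filter is the identity.
#'
#' @param table A [feature_table()].
#' @param y Binary 0/1 labels (used only to fit the weights that decide
#'   which pair member to drop).
#' @param threshold `T` in (0, 1); default 0.95.
#' @return A [selection_result()] of the surviving features, with one trace
#'   row per removal pass.
#' @export
haff_filter <- function(table, y, threshold = 0.95) {
  if (threshold <= 0 || threshold >= 1) {
    stop_efs("threshold must lie in (0, 1)", class = "parameter_error")
  }
  active <- table$feature_names
  trace <- list()
  removed <- character()
  repeat {
    X <- table$values[, active, drop = FALSE]
    sds <- apply(X, 2L, stats::sd)
    nz <- sds > 0
    if (sum(nz) < 2L) break
    C <- stats::cor(X[, nz, drop = FALSE])
    C[upper.tri(C, diag = TRUE)] <- 0
    hits <- which(C < -threshold, arr.ind = TRUE)
    if (nrow(hits) == 0L) break
    model <- fit_lda(X, y)
    imp <- feature_importance(model)
    bacc <- balanced_accuracy(y, predict(model, X))
    trace[[length(trace) + 1L]] <- data.frame(
      active_features = length(active), bacc_mean = bacc, bacc_sd = 0)
    nz_names <- colnames(C)
    drop_now <- unique(vapply(seq_len(nrow(hits)), function(i) {
      a <- nz_names[hits[i, 1L]]
      b <- nz_names[hits[i, 2L]]
      if (imp[[a]] < imp[[b]]) a else b
    }, character(1)))
    removed <- c(removed, drop_now)
    active <- setdiff(active, drop_now)
  }
  selection_result(active, "HAFF", list(threshold = threshold), table,
    trace = if (length(trace)) do.call(rbind, trace) else empty_trace(),
    details = list(removed = removed))
}
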