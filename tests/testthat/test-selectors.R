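# Random selection, correlation clustering (HCFR), recursive elimination
# (RFE / RFE-CV) and the anti-correlated-pair prefilter (HAFF).

test_that("random selection is uniform, seeded and respects p", {
  sim <- planted_dataset(d = 120, n = 20, n_informative = 0,
                         effect_size = 0, seed = 1)
  tab <- sim$table

  all_of_them <- select_random(tab, p = 120, seed = 1)
  expect_identical(all_of_them$selected, tab$feature_names)

  r <- select_random(tab, p = 10, seed = 3)
  expect_selection_valid(r, tab)
  expect_length(r$selected, 10)
  expect_identical(select_random(tab, p = 10, seed = 3)$selected, r$selected)
  expect_error(select_random(tab, p = 121), class = "parameter_error")

  # binomial oracle: over many seeded draws each feature appears with
  # frequency 1/12 within 3 standard errors
  n_draws <- 4000L
  counts <- integer(120)
  names(counts) <- tab$feature_names
  for (s in seq_len(n_draws)) {
    sel <- select_random(tab, p = 10, seed = s)$selected
    counts[sel] <- counts[sel] + 1L
  }
  q <- 10 / 120
  se <- sqrt(q * (1 - q) / n_draws)
  expect_true(all(abs(counts / n_draws - q) <= 3.5 * se))
})

test_that("correlation clustering keeps one representative per duplicate pair", {
  set.seed(2)
  a <- rnorm(100); c <- rnorm(100); e <- rnorm(100)
  tab <- mat_table(cbind(A = a, B = a, C = c, D = c, E = e))
  r <- select_hcfr(tab, max_correlation = 0.95, seed = 1)
  expect_length(r$selected, 3)
  expect_equal(sum(r$selected %in% c("A", "B")), 1)
  expect_equal(sum(r$selected %in% c("C", "D")), 1)
  expect_true("E" %in% r$selected)
})

test_that("independent features below the threshold are all retained", {
  sim <- planted_dataset(d = 15, n = 300, n_informative = 0,
                         effect_size = 0, seed = 5)
  C <- cor(sim$table$values)
  diag(C) <- 0
  stopifnot(max(abs(C)) < 0.95)  # fixture sanity
  r <- select_hcfr(sim$table, max_correlation = 0.95, seed = 2)
  expect_setequal(r$selected, sim$table$feature_names)
})

test_that("constant features form their own clusters", {
  set.seed(3)
  X <- cbind(matrix(rnorm(50 * 3), 50, 3), 7)
  tab <- mat_table(X, c("A", "B", "C", "const"))
  r <- select_hcfr(tab, max_correlation = 0.9, seed = 1)
  expect_true("const" %in% r$selected)
  expect_equal(r$params$n_constant, 1L)
})

test_that("recursive elimination reaches the target with a full trace", {
  sim <- planted_dataset(d = 40, n = 200, n_informative = 2,
                         effect_size = 2, seed = 6)
  y <- sim$labels$labels$pathologic

  full <- select_rfe(sim$table, y, target_p = 40)
  expect_identical(full$selected, sim$table$feature_names)
  expect_equal(nrow(full$trace), 0L)

  r <- select_rfe(sim$table, y, target_p = 10)
  expect_selection_valid(r, sim$table)
  expect_length(r$selected, 10)
  expect_equal(r$trace$active_features, seq(40, 11))
  expect_true(all(diff(r$trace$active_features) == -1))
})

test_that("elimination recovers a planted informative feature", {
  sim <- planted_dataset(d = 25, n = 252, n_informative = 1,
                         effect_size = 3, seed = 7)
  y <- sim$labels$labels$pathologic
  planted <- sim$informative$pathologic
  # oracle: the planted feature is uniquely informative by single-feature
  # resubstitution accuracy
  singles <- vapply(sim$table$feature_names, function(f) {
    X <- sim$table$values[, f, drop = FALSE]
    m <- fit_lda(X, y)
    balanced_accuracy(y, predict(m, X))
  }, numeric(1))
  expect_equal(names(which.max(singles)), planted)

  r <- select_rfe(sim$table, y, target_p = 1)
  expect_identical(r$selected, planted)
})

test_that("single-step elimination paths are nested", {
  sim <- planted_dataset(d = 20, n = 150, n_informative = 3,
                         effect_size = 1, seed = 8)
  y <- sim$labels$labels$pathologic
  r10 <- select_rfe(sim$table, y, target_p = 10)
  r5 <- select_rfe(sim$table, y, target_p = 5)
  expect_true(all(r5$selected %in% r10$selected))
})

test_that("cross-validated elimination picks the count from the trade-off rule", {
  sim <- planted_dataset(d = 12, n = 150, n_informative = 1,
                         effect_size = 3, seed = 9)
  y <- sim$labels$labels$pathologic
  scheme <- cv_scheme(5, seed = 2)

  r <- select_rfe_cv_auto(sim$table, y, scheme, trade_off_sd = 1)
  expect_true(sim$informative$pathologic %in% r$selected)
  expect_equal(length(r$selected), r$details$chosen_p)

  # trade_off_sd = 0 degenerates to the argmax of the mean path
  r0 <- select_rfe_cv_auto(sim$table, y, scheme, trade_off_sd = 0)
  path <- r0$trace[r0$trace$bacc_sd > 0 | TRUE, ]
  best <- max(path$bacc_mean)
  cands <- path$active_features[path$bacc_mean >= best]
  expect_equal(r0$details$chosen_p, min(cands))

  # flat noise path: the minimum evaluated count wins under a generous
  # trade-off
  noise <- planted_dataset(d = 8, n = 150, n_informative = 0,
                           effect_size = 0, seed = 10)
  rn <- select_rfe_cv_auto(noise$table, noise$labels$labels$pathologic,
                           scheme, trade_off_sd = 5)
  expect_equal(rn$details$chosen_p, 1L)
})

test_that("the anti-correlated-pair filter removes exactly one member per pair", {
  tab <- anti_pair_table(n = 200, d_noise = 6, rho = 0.99, seed = 1)
  y <- as.integer(tab$values[, "a1"] + rnorm(200, sd = 0.5) > 0)
  r <- haff_filter(tab, y, threshold = 0.95)
  expect_equal(length(r$details$removed), 1L)
  expect_true(r$details$removed %in% c("a1", "a2"))
  expect_setequal(r$selected, setdiff(tab$feature_names, r$details$removed))

  # no pair below -T: identity
  noise <- planted_dataset(d = 10, n = 100, n_informative = 0,
                           effect_size = 0, seed = 2)
  y2 <- noise$labels$labels$pathologic
  r2 <- haff_filter(noise$table, y2, threshold = 0.95)
  expect_identical(r2$selected, noise$table$feature_names)
  expect_equal(nrow(r2$trace), 0L)
})

test_that("the filter drops the pair member the classifier leans on least", {
  tab <- anti_pair_table(n = 300, d_noise = 4, rho = 0.99, seed = 4)
  y <- as.integer(tab$values[, "a1"] + rnorm(300, sd = 0.3) > 0)
  model <- fit_lda(tab, y)
  imp <- feature_importance(model)
  weaker <- if (imp[["a1"]] < imp[["a2"]]) "a1" else "a2"
  r <- haff_filter(tab, y, threshold = 0.95)
  expect_identical(r$details$removed, weaker)
})

test_that("every selector is a pure function of data, params and seed", {
  sim <- planted_dataset(d = 15, n = 120, n_informative = 2,
                         effect_size = 1.5, seed = 11)
  y <- sim$labels$labels$pathologic
  expect_identical(select_hcfr(sim$table, 0.9, seed = 5)$selected,
                   select_hcfr(sim$table, 0.9, seed = 5)$selected)
  expect_identical(select_random(sim$table, 4, seed = 5)$selected,
                   select_random(sim$table, 4, seed = 5)$selected)
  expect_identical(select_rfe(sim$table, y, 5)$selected,
                   select_rfe(sim$table, y, 5)$selected)
})
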