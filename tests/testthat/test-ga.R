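# Genetic subset search: fitness definition, elitism, determinism, and
# agreement with exhaustive enumeration at desk scale.

test_that("fitness combines the cardinality penalty and negative accuracy", {
  sim <- planted_dataset(d = 8, n = 80, n_informative = 2,
                         effect_size = 1.5, seed = 1)
  y <- sim$labels$labels$pathologic
  scheme <- cv_scheme(4, seed = 1)
  p <- 3

  # |P| <= p: no penalty, fitness is exactly the negative CV accuracy
  mask <- rep(FALSE, 8); mask[1:3] <- TRUE
  acc <- cv_bacc(sim$table$values[, mask, drop = FALSE], y, scheme)$mean
  expect_equal(ga_fitness(mask, sim$table, y, p, scheme = scheme), -acc)

  # |P| = p + 4: penalty of exactly 4 on top
  mask2 <- rep(FALSE, 8); mask2[1:7] <- TRUE
  acc2 <- cv_bacc(sim$table$values[, mask2, drop = FALSE], y, scheme)$mean
  expect_equal(ga_fitness(mask2, sim$table, y, p, scheme = scheme), 4 - acc2)

  # empty mask scores chance
  expect_equal(ga_fitness(rep(FALSE, 8), sim$table, y, p, scheme = scheme),
               -0.5)

  # the printed penalty form rewards small sets and never penalises excess
  expect_equal(
    ga_fitness(mask, sim$table, y, target_p = 5, scheme = scheme,
               penalty_form = "printed_min"),
    (3 - 5) - acc)
  expect_equal(
    ga_fitness(mask2, sim$table, y, target_p = 3, scheme = scheme,
               penalty_form = "printed_min"),
    -acc2)
})

test_that("equal-accuracy masks order by size under the corrected penalty", {
  # direct consequence of the penalty formula, checked through the API:
  # adding the penalty to a common accuracy ranks the smaller set first
  sim <- planted_dataset(d = 6, n = 60, n_informative = 0,
                         effect_size = 0, seed = 2)
  y <- sim$labels$labels$pathologic
  scheme <- cv_scheme(3, seed = 2)
  p <- 2
  m_small <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m_big <- rep(TRUE, 6)
  f_small <- ga_fitness(m_small, sim$table, y, p, scheme = scheme)
  f_big <- ga_fitness(m_big, sim$table, y, p, scheme = scheme)
  # the big mask carries a +4 penalty; accuracies differ by far less
  expect_lt(f_small, f_big)
})

test_that("the search is seeded, elitist and matches brute force on a small problem", {
  sim <- planted_dataset(d = 10, n = 60, n_informative = 2,
                         effect_size = 1.5, seed = 3)
  y <- sim$labels$labels$pathologic
  scheme <- cv_scheme(3, seed = 3)

  r <- select_ga(sim$table, y, target_p = 3, population = 30,
                 generations = 60, seed = 9, scheme = scheme)
  expect_selection_valid(r, sim$table)
  r2 <- select_ga(sim$table, y, target_p = 3, population = 30,
                  generations = 60, seed = 9, scheme = scheme)
  expect_identical(r$selected, r2$selected)
  expect_true(all(diff(r$details$generation_best) <= 1e-12))

  # exhaustive enumeration over all 2^10 masks
  d <- 10
  best <- Inf
  for (code in 0:(2^d - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(0:(d - 1))) > 0)
    f <- ga_fitness(mask, sim$table, y, target_p = 3, scheme = scheme)
    if (f < best) best <- f
  }
  expect_equal(r$details$best_fitness, best, tolerance = 1e-12)
})

test_that("population below four is rejected", {
  sim <- planted_dataset(d = 5, n = 40, n_informative = 0,
                         effect_size = 0, seed = 4)
  expect_error(select_ga(sim$table, sim$labels$labels$pathologic,
                         target_p = 2, population = 3),
               class = "parameter_error")
})

test_that("dual-phase composition restricts the search to the first-phase set", {
  sim <- simulate_dataset(study_shape_config(seed = 5))
  y <- sim$labels$labels$pathologic
  scheme <- cv_scheme(3, seed = 5)
  r <- dual_phase(sim$table, y, phase1 = "SDA", q = 30, p = 8,
                  haff = 0.95, scheme = scheme, seed = 5,
                  ga_args = list(population = 20, generations = 20))
  expect_lte(length(r$selected), 8)
  expect_true(all(r$selected %in% r$details$phase1$selected))
  expect_equal(r$selector_name, "SDA30GA8_HAFF_BACC")
})

test_that("a full-width first phase degenerates to plain genetic search", {
  sim <- planted_dataset(d = 12, n = 80, n_informative = 2,
                         effect_size = 1.5, seed = 6)
  y <- sim$labels$labels$pathologic
  scheme <- cv_scheme(3, seed = 6)
  ga_args <- list(population = 16, generations = 15)
  dp <- dual_phase(sim$table, y, phase1 = "RFE", q = 12, p = 4,
                   scheme = scheme, seed = 7, ga_args = ga_args)
  plain <- do.call(select_ga, c(list(table = sim$table, y = y, target_p = 4,
                                     seed = 7, scheme = scheme), ga_args))
  expect_identical(dp$selected, plain$selected)
})
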