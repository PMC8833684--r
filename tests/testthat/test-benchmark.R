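# Repetition harness: naming grammar, distributions, frequency tables,
# determinism and persistence.

test_that("run names follow the naming grammar", {
  expect_equal(make_run_name("SDA", 50, "GA", 10, haff = TRUE),
               "SDA50GA10_HAFF_BACC")
  expect_equal(make_run_name("GA", 10), "GA10_nohaff_BACC")
  expect_equal(make_run_name("RFE", 51, haff = TRUE), "RFE51_HAFF_BACC")
  expect_equal(make_run_name("HCFR"), "HCFR_nohaff_BACC")
  expect_error(make_run_name("PCA", 10), class = "parameter_error")

  expect_equal(efsbench:::spec_run_name(
    selector_spec("sda-ga", p = 10, q = 50, haff = TRUE)),
    "SDA50GA10_HAFF_BACC")
  expect_equal(efsbench:::spec_run_name(selector_spec("rnd", p = 51)),
               "RND51_nohaff_BACC")
})

test_that("selecting every feature reproduces the baseline accuracy", {
  sim <- planted_dataset(d = 20, n = 120, n_informative = 2,
                         effect_size = 1.5, seed = 1)
  rep1 <- run_benchmark(sim$table, sim$labels,
                        list(selector_spec("rnd", p = 20)),
                        repetitions = 1, cv = cv_scheme(5), base_seed = 0)
  # with base_seed 0 and one repetition, the repetition fold seed is 1;
  # compare against the baseline at that seed
  base <- cv_bacc(sim$table, sim$labels$labels$pathologic,
                  cv_scheme(5, seed = 1))$mean
  expect_equal(unname(rep1$distributions[[1]]), base)
})

test_that("distributions, frequencies and determinism hold at small R", {
  sim <- planted_dataset(d = 15, n = 100, n_informative = 2,
                         effect_size = 1.5, seed = 2)
  specs <- list(selector_spec("rnd", p = 4),
                selector_spec("rfe", p = 3))
  a <- run_benchmark(sim$table, sim$labels, specs, repetitions = 5,
                     cv = cv_scheme(4), base_seed = 7)
  b <- run_benchmark(sim$table, sim$labels, specs, repetitions = 5,
                     cv = cv_scheme(4), base_seed = 7)
  expect_identical(a$distributions, b$distributions)
  expect_identical(a$frequency_tables, b$frequency_tables)

  expect_true(all(lengths(a$distributions) == 5L))
  for (ft in a$frequency_tables) {
    expect_true(all(ft$frequency_denominator == 5L))
    expect_true(all(ft$frequency_numerator <= 5L))
  }
  # exact-p selector: numerators sum to R * p
  ft_rnd <- a$frequency_tables[["RND4_nohaff_BACC|pathologic"]]
  expect_equal(sum(ft_rnd$frequency_numerator), 5L * 4L)
})

test_that("frequency tables render counts per repetition and sort by class", {
  results <- list(c("original_shape_SurfaceVolumeRatio",
                    "original_firstorder_Skewness"),
                  c("original_shape_SurfaceVolumeRatio"),
                  c("original_shape_SurfaceVolumeRatio",
                    "original_glszm_ZoneEntropy"))
  ft <- selection_frequency_table(results)
  always <- ft[ft$feature_name == "original_shape_SurfaceVolumeRatio", ]
  expect_equal(always$frequency, "3/3")
  expect_equal(always$type_group, "shape")
  skew <- ft[ft$feature_name == "original_firstorder_Skewness", ]
  expect_equal(skew$frequency, "1/3")
  expect_equal(skew$type_group, "intensity")
  # class order follows the catalog enum
  expect_equal(ft$feature_class,
               c("first_order", "shape_3d", "glszm"))

  ft10 <- selection_frequency_table(rep(list("original_glcm_Idm"), 7),
                                    denominator = 10)
  expect_equal(ft10$frequency, "7/10")

  expect_equal(nrow(selection_frequency_table(list())), 0L)
})

test_that("distribution summaries carry order statistics and the baseline", {
  sim <- planted_dataset(d = 10, n = 80, n_informative = 1,
                         effect_size = 2, seed = 3)
  rep1 <- run_benchmark(sim$table, sim$labels,
                        list(selector_spec("rnd", p = 3)),
                        repetitions = 5, cv = cv_scheme(4), base_seed = 1)
  s <- summarize_distributions(rep1)
  expect_equal(nrow(s), 1L)
  expect_equal(s$baseline, unname(rep1$baseline_bacc["pathologic"]))
  v <- rep1$distributions[[1]]
  expect_equal(s$median, unname(quantile(v, 0.5)))
  expect_equal(s$min, min(v))
  expect_equal(s$max, max(v))

  # direct order-statistics check of the quantile convention
  fake <- rep1
  fake$distributions[[1]] <- c(0.6, 0.7, 0.8, 0.9, 1.0)
  expect_equal(summarize_distributions(fake)$median, 0.8)
})

test_that("reports survive a write/read round trip exactly", {
  sim <- planted_dataset(d = 10, n = 80, n_informative = 1,
                         effect_size = 2, seed = 4)
  rep1 <- run_benchmark(sim$table, sim$labels,
                        list(selector_spec("rnd", p = 3)),
                        repetitions = 3, cv = cv_scheme(4), base_seed = 2)
  dir <- withr::local_tempdir()
  write_report(rep1, dir)
  back <- read_report(dir)
  expect_equal(back$distributions, rep1$distributions)
  expect_equal(back$baseline_bacc, rep1$baseline_bacc)
  expect_equal(lapply(back$frequency_tables, function(x) x$frequency_numerator),
               lapply(rep1$frequency_tables, function(x) x$frequency_numerator))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "selection_frequencies.csv")))
})

test_that("persistent selector failures abort the run with a summary", {
  sim <- planted_dataset(d = 8, n = 60, n_informative = 0,
                         effect_size = 0, seed = 5)
  broken <- selector_spec("rfe", p = 3, params = list(step_n = 0L))
  expect_error(
    run_benchmark(sim$table, sim$labels, list(broken), repetitions = 2,
                  cv = cv_scheme(3), base_seed = 1),
    class = "benchmark_abort"
  )
})
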