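# Fixture builders shared across test files. All fixtures are generated
# in code under fixed seeds; nothing is stored on disk.

# Independent-feature dataset with a planted informative subset.
planted_dataset <- function(d, n = 252L, n_informative = 1L,
                            effect_size = 3, seed = 1L,
                            prevalence = c(pathologic = 0.5)) {
  cfg <- synthetic_config(
    n_samples = n, n_features = d,
    n_informative = n_informative, effect_size = effect_size,
    prevalence = prevalence, seed = seed
  )
  simulate_dataset(cfg)
}

# Plain numeric-matrix feature table; generic names unless the matrix
# (or the caller) provides them.
mat_table <- function(X, names = NULL) {
  if (is.null(names)) {
    names <- colnames(X)
    if (is.null(names)) names <- sprintf("F%02d", seq_len(ncol(X)))
  }
  colnames(X) <- names
  feature_table(X)
}

# Table containing an injected anti-correlated pair (cols a1/a2 at corr
# close to -rho) plus independent noise columns.
anti_pair_table <- function(n = 200L, d_noise = 6L, rho = 0.99,
                            seed = 1L) {
  set.seed(seed)
  z <- rnorm(n)
  a1 <- z
  a2 <- -rho * z + sqrt(1 - rho^2) * rnorm(n)
  X <- cbind(a1 = a1, a2 = a2,
             matrix(rnorm(n * d_noise), n,
                    dimnames = list(NULL, sprintf("N%02d", seq_len(d_noise)))))
  feature_table(X)
}

expect_selection_valid <- function(res, table) {
  expect_s3_class(res, "selection_result")
  expect_false(anyDuplicated(res$selected) > 0)
  expect_true(all(res$selected %in% table$feature_names))
}
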