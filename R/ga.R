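# Genetic-algorithm subset search over binary feature masks.

#' Weighted-sum fitness of a feature mask
#'
#' The subset-search objective combines a cardinality penalty and the
#' classifier's performance into a single scalar to minimise:
#' `lambda1 * c1(|P|) + lambda2 * c2(P)`, where `c2` is the negative
#' cross-validated balanced accuracy of the linear discriminant restricted
#' to the masked features (an empty mask scores chance, `c2 = -0.5`), and
#' `c1` penalises the feature count relative to the target `p`. The default
#' penalty form `"corrected_max"` is `max(|P| - p, 0)`: feature counts at
#' or below the target are free, every feature beyond it costs
#' `lambda1`. The alternative `"printed_min"` form `min(|P| - p, 0)` is
#' also available; it rewards sets smaller than `p` instead of penalising
#' excess, and is retained for comparison only.
#'
#' @param mask Logical/0-1 vector over the table's features.
#' @param table A [feature_table()].
#' @param y Binary 0/1 labels.
#' @param target_p Target feature count `p`.
#' @param lambda1,lambda2 Penalty and accuracy weights (defaults 1).
#' @param scheme [cv_scheme()] for the accuracy term.
#' @param penalty_form `"corrected_max"` (default) or `"printed_min"`.
#' @return Scalar fitness (lower is better).
#' @export
ga_fitness <- function(mask, table, y, target_p, lambda1 = 1, lambda2 = 1,
                       scheme = cv_scheme(),
                       penalty_form = c("corrected_max", "printed_min")) {
  penalty_form <- match.arg(penalty_form)
  mask <- as.logical(mask)
  if (length(mask) != length(table$feature_names)) {
    stop_efs("mask length must equal feature count",
      class = "parameter_error")
  }
  size <- sum(mask)
  c1 <- switch(penalty_form,
    corrected_max = max(size - target_p, 0),
    printed_min = min(size - target_p, 0)
  )
  c2 <- if (size == 0L) {
    -0.5
  } else {
    -cv_bacc(table$values[, mask, drop = FALSE], y, scheme)$mean
  }
  lambda1 * c1 + lambda2 * c2
}

#' Genetic-algorithm feature selection (GA)
#'
#' Single-objective binary-mask genetic search minimising [ga_fitness()]:
#' tournament selection (size 3), uniform crossover, per-bit flip mutation
#' and elitism of one. The feature-count limit is "soft": the best mask may
#' hold fewer than `target_p` features, and may exceed it only if the
#' penalised fitness still wins. The run is a pure function of
#' (data, params, seed); fitness values are cached per mask.
#'
#' @param table A [feature_table()].
#' @param y Binary 0/1 labels.
#' @param target_p Target feature count.
#' @param lambda1,lambda2 Fitness weights (defaults 1).
#' @param population Population size (>= 4, default 60).
#' @param generations Number of generations (default 150).
#' @param crossover_prob Probability of crossover per offspring pair
#'   (default 0.7).
#' @param mutation_prob Per-bit flip probability; default `1/d`.
#' @param seed Integer seed.
#' @param scheme [cv_scheme()] for the fitness.
#' @param penalty_form See [ga_fitness()].
#' @return A [selection_result()]; `details` carries `best_fitness` and the
#'   per-generation best-fitness sequence `generation_best`
#'   (non-increasing under elitism).
#' @export
select_ga <- function(table, y, target_p, lambda1 = 1, lambda2 = 1,
                      population = 60L, generations = 150L,
                      crossover_prob = 0.7, mutation_prob = NULL,
                      seed = 1L, scheme = cv_scheme(),
                      penalty_form = c("corrected_max", "printed_min")) {
  penalty_form <- match.arg(penalty_form)
  d <- length(table$feature_names)
  target_p <- assert_scalar_int(target_p, "target_p")
  if (target_p > d) stop_efs("target_p exceeds d", class = "parameter_error")
  population <- assert_scalar_int(population, "population", 4L)
  generations <- assert_scalar_int(generations, "generations", 1L)
  if (is.null(mutation_prob)) mutation_prob <- 1 / d

  cache <- new.env(parent = emptyenv())
  evaluate <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- ga_fitness(mask, table, y, target_p, lambda1, lambda2, scheme,
                      penalty_form)
    cache[[key]] <- val
    val
  }

  with_local_seed(seed, {
    # initial population: exact-p masks (half) and Bernoulli(p/d) masks
    pop <- lapply(seq_len(population), function(i) {
      m <- rep(FALSE, d)
      if (i <= population %/% 2) {
        m[sample.int(d, target_p)] <- TRUE
      } else {
        m <- stats::runif(d) < target_p / d
      }
      m
    })
    fit <- vapply(pop, evaluate, numeric(1))
    gen_best <- numeric(generations)
    for (g in seq_len(generations)) {
      elite <- which.min(fit)
      newpop <- list(pop[[elite]])
      while (length(newpop) < population) {
        tourn <- function() {
          cand <- sample.int(population, 3L)
          pop[[cand[which.min(fit[cand])]]]
        }
        p1 <- tourn(); p2 <- tourn()
        if (stats::runif(1) < crossover_prob) {
          swap <- stats::runif(d) < 0.5
          c1 <- ifelse(swap, p2, p1)
          c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          flip <- stats::runif(d) < mutation_prob
          child <- xor(child, flip)
          if (length(newpop) < population) {
            newpop[[length(newpop) + 1L]] <- child
          }
        }
      }
      pop <- newpop
      fit <- vapply(pop, evaluate, numeric(1))
      gen_best[g] <- min(fit)
    }
    best <- which.min(fit)
    sel <- table$feature_names[pop[[best]]]
    selection_result(sel, "GA",
      list(target_p = target_p, lambda1 = lambda1, lambda2 = lambda2,
           population = population, generations = generations,
           crossover_prob = crossover_prob, mutation_prob = mutation_prob,
           penalty_form = penalty_form),
      table, seed = seed,
      details = list(best_fitness = fit[best], generation_best = gen_best,
                     n_evaluations = length(ls(cache))))
  })
}

#' Dual-phase feature selection
#'
#' Two-stage elimination: an optional anti-correlated-pair prefilter
#' ([haff_filter()]), a first phase reducing the feature set to a moderate
#' size `q` with a non-combinatorial selector (sparse discriminant or
#' recursive elimination), then a genetic search restricted to those `q`
#' features down to the target `p`. Naming follows the benchmark grammar,
#' e.g. `SDA50GA10_HAFF_BACC`.
#'
#' @param table A [feature_table()].
#' @param y Binary 0/1 labels.
#' @param phase1 `"SDA"` or `"RFE"`.
#' @param q First-phase target feature count.
#' @param p Final target feature count (`p <= q`).
#' @param haff Optional prefilter threshold in (0, 1).
#' @param scheme [cv_scheme()] shared by both phases.
#' @param seed Integer seed (drives the GA).
#' @param ga_args Named list of overrides passed to [select_ga()]
#'   (e.g. `population`, `generations`).
#' @return A [selection_result()] named by the run grammar; `details$phase1`
#'   holds the first-phase result.
#' @export
dual_phase <- function(table, y, phase1 = c("SDA", "RFE"), q, p,
                       haff = NULL, scheme = cv_scheme(), seed = 1L,
                       ga_args = list()) {
  phase1 <- match.arg(phase1)
  q <- assert_scalar_int(q, "q")
  p <- assert_scalar_int(p, "p")
  if (p > q || q > length(table$feature_names)) {
    stop_efs("need p <= q <= d", class = "parameter_error")
  }
  tab <- table
  pre <- NULL
  if (!is.null(haff)) {
    pre <- haff_filter(tab, y, threshold = haff)
    tab <- ft_subset(tab, pre$selected)
    if (q > length(tab$feature_names)) {
      stop_efs("phase-1 target q exceeds post-prefilter feature count",
        class = "parameter_error")
    }
  }
  r1 <- switch(phase1,
    SDA = select_sda(tab, y, target_p = q, scheme = scheme),
    RFE = select_rfe(tab, y, target_p = q)
  )
  tab2 <- ft_subset(tab, r1$selected)
  r2 <- do.call(select_ga, c(
    list(table = tab2, y = y, target_p = p, seed = seed, scheme = scheme),
    ga_args
  ))
  name <- make_run_name(phase1, q, "GA", p, haff = !is.null(haff))
  res <- selection_result(r2$selected, name,
    list(phase1 = phase1, q = q, p = p, haff = haff),
    table,
    trace = rbind(if (is.null(pre)) empty_trace() else pre$trace, r1$trace),
    seed = seed,
    details = list(phase1 = r1, ga = r2$details))
  res
}
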