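---
title: "Methods: benchmarking eliminative feature selection with efsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking eliminative feature selection with efsbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`efsbench` benchmarks *eliminative* feature selection (EFS) on radiomic
feature tables: every selector returns a subset of the original columns and
never recombines or transforms them. The package provides

* a fixed 120-feature radiomic catalog and CSV/TSV IO with validation,
* a seeded synthetic generator with planted correlation structure and
  planted informative features,
* a binary linear discriminant (LDA) wrapper scored by balanced accuracy,
* six selector families (random, hierarchical correlation filtering,
  recursive feature elimination with and without CV-chosen size, sparse
  discriminant analysis, genetic search) plus an anti-correlation prefilter
  and a dual-phase composition,
* a repetition harness producing balanced-accuracy distributions and
  per-feature selection-frequency tables.

## The classifier wrapper

For a binary task with class means $\mu_0, \mu_1$ and pooled covariance
$\Sigma$, the discriminant weights are $\omega = \Sigma^{-1}(\mu_1 - \mu_0)$
and a sample $x$ is assigned class 1 iff
$\omega \cdot x > \omega \cdot \tfrac{\mu_0 + \mu_1}{2} - \log(\pi_1/\pi_0)$.

When the feature count $d \ge n - 2$ or the pooled covariance is
ill-conditioned (reciprocal condition number below `1e-10`), a
Ledoit–Wolf-style shrinkage toward $\bar{\sigma}^2 I$ is applied, with the
analytic intensity floored at `1e-4`. Shrinkage is deliberately *not*
applied otherwise, so on well-conditioned data the rule keeps LDA's
invariance to affine per-feature rescaling.

Performance is balanced accuracy,
$\mathrm{BACC} = (\mathrm{sens} + \mathrm{spec})/2$, which is insensitive
to the strong class imbalance typical of these tasks (e.g. 182 vs 70). A
fold with only one class present raises a typed `undefined_metric_error`
rather than returning a silent `NaN`; stratified folds (the default) avoid
this by construction. Cross-validated BACC reports the mean over folds and
the population standard deviation (division by $k$).

## Synthetic data

`synthetic_config()` describes a multivariate-normal feature matrix:
correlated blocks (size, target $r$), anti-correlated pairs (target $r<0$),
and independent remainder columns. The target correlation matrix is checked
for positive semi-definiteness; if eigenvalue clipping plus diagonal
renormalisation moves any *target* entry by more than 0.02 the
configuration is rejected (`configuration_error`) rather than silently
altered. Labels come from a logistic latent score over the planted
informative features (placed among the independent columns) and are
rank-thresholded so each task hits its configured prevalence *exactly*.
Nested tasks reuse the first half of the parent's informative features, so
"nested positive within parent" holds by construction; when prevalences of
a task and its complement sum to 1 the complement uses the negated latent
score.

`study_shape_config()` is a convenience config with the benchmark's study
shape: 252 samples × 120 features, four correlated blocks
(6 @ 0.97, 5 @ 0.96, 4 @ 0.98, 4 @ 0.95), two anti-pairs at −0.97, 10
informative features, and task prevalences 182/252, 52/252 (nested) and
70/252 (complement). Its `effect_size = 1.6` was calibrated **once**,
before any test was written against it, by scanning effect sizes and
choosing the value whose population-optimal BACC (≈0.89, Monte Carlo via
`population_bacc()`) matches a realistically strong radiomic signal; it was
not tuned against test outcomes afterwards.

Known limitations: the generator is Gaussian (no heavy tails or mixed
scales as real radiomics has), correlation structure is block-wise rather
than hierarchically nested, and informative features are independent of the
correlated blocks, which makes redundancy-removal tasks cleaner than in
real data.

## Selectors

All selectors return a `selection_result` whose trace has strictly
decreasing feature counts; all are pure functions of (data, parameters,
seed) via `with_local_seed()`.

* **RND** — uniform sample of `p` features; the reference noise floor.
* **HCFR** — hierarchical correlation-based filtering: single-linkage
  `hclust` on distance $1-|r|$, cut at height $1-S$, one random
  representative per cluster. Single linkage makes the guarantee provable:
  any two features in different clusters have $|r| \le S$. Constant
  features (undefined $r$) become singleton clusters.
* **RFE** — iteratively fit LDA, drop the feature(s) with smallest
  $|\omega|$ (ties broken toward the larger column index), until `p`
  remain. `select_rfe_cv_auto()` scores each count by CV BACC using the
  *mean per-fold* $|\omega|$ for the elimination order and picks the
  smallest count whose mean is within `trade_off_sd` standard deviations of
  the best.
* **HAFF** — highly anti-correlated feature filter: while any pair has
  $r < -T$ (default $T = 0.95$), remove the member with the smaller
  $|\omega|$ in a full LDA fit, refit, repeat.
* **SDA** — sparse discriminant analysis as penalised optimal scoring,
  $\min_\beta \lVert y_c - X_s\beta\rVert^2 + \lambda\lVert\beta\rVert_1
  + \gamma\lVert\beta\rVert_2^2$, solved by `glmnet` (mapping
  $L\alpha = \lambda/2n$, $L(1-\alpha) = \gamma/n$; `standardize = FALSE`,
  no intercept, `thresh = 1e-11`, a 25-step warm path ending at the target
  $\lambda$). The support size is tuned to exactly `p` by bisection in
  $\log\lambda$ (tolerance `1e-4` on the log bracket) starting from the
  null threshold $\lambda_0 = 2\max_j |x_j'y_c|$; an unreachable
  cardinality yields the nearest support plus a "cardinality miss" warning
  and `details$cardinality_miss = TRUE`. At $\lambda=\gamma=0$ the solver
  switches to the normal equations. Default $\gamma = 1$ keeps the
  elastic-net path stable among near-duplicate features.
* **GA** — hand-written binary-mask genetic algorithm (no suitable GA
  package is available in the target environment): tournament size 3,
  uniform crossover 0.7, bit-flip mutation $1/d$, elitism 1, defaults
  population 60 / generations 150, fitness cache keyed by the bit string,
  initial population half exact-`p` masks and half Bernoulli($p/d$). The
  fitness is $\lambda_1\max(|P|-p, 0) - \lambda_2\,\mathrm{BACC_{CV}}$;
  the `max` corrects an apparent transcription slip in the printed form
  (with `min`, the penalty would *reward* ever-smaller subsets and never
  penalise oversized ones, contradicting its stated purpose); the printed
  variant remains available via `penalty_form = "printed_min"`. An empty
  mask scores chance (−0.5).
* **Dual phase** — a wide phase-1 selector (SDA or RFE) to `q` features,
  optionally HAFF, then GA to `p` within the survivors.

Run names follow the grammar
`<Phase1><q>[<Phase2><p>]_(HAFF|nohaff)_BACC`, e.g. `SDA50GA10_HAFF_BACC`.

## Benchmark harness

`run_benchmark()` repeats each selector × task `R` times (default 100);
repetition `i` uses seed `base_seed + i` for both the selector and the CV
fold split, so distributions reflect both sampling and algorithmic
randomness yet the whole report is bit-reproducible. Per run it records
CV BACC (and resubstitution BACC) of an LDA refit on the selected subset,
plus a selection-frequency table (`num/R` per feature, annotated with
catalog class and shape/intensity/texture group). A baseline all-feature
CV BACC per task is stored for reference. More than 20% failed repetitions
aborts with `benchmark_abort`; isolated failures are recorded in
`$failures`. `write_report()`/`read_report()` round-trip the report
through JSON/CSV bit-exactly (numbers serialised at 17 significant
digits).

## Problem sizes exercised in the tests

* GA vs exhaustive enumeration: $d = 12$ (4096 masks), $n = 60$, 3-fold CV.
* RFE recovery: full study width $d = 120$, $n = 252$, one planted feature.
* SDA exact cardinality: study shape, $p \in \{10, 51\}$.
* Dual-phase recovery: $d = 60$, $n = 252$, three planted features,
  `SDA30GA3`.
* Harness determinism: study shape, $R = 20$, `RND51` and
  `SDA50GA10_HAFF` with a reduced GA budget.

## Command line

A thin CLI ships at `system.file("scripts", "efsb", package = "efsbench")`
with subcommands `simulate`, `baseline`, `select`, `bench` and `report`;
YAML configs mirror `synthetic_config()` and `selector_spec()`.

## Open design decisions

* The shrinkage trigger (`d >= n - 2` or rcond < 1e-10) is a heuristic;
  a cross-validated shrinkage intensity would be more principled but
  costs a nested CV per fit.
* The SDA-to-`glmnet` mapping fixes $\gamma$ and bisects only $\lambda$;
  a 2-D search could trade sparsity against grouping behaviour.
* Selection frequencies are reported per feature; aggregating by
  correlated cluster would better reflect redundancy but requires a
  cluster definition that is itself a modelling choice.
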