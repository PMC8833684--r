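# Repetition harness: baseline classifier, seeded repetition loop over
# selector specifications and tasks, BACC distributions and
# selection-frequency tables.

#' Compose a benchmark run name
#'
#' Runs are named by the grammar
#' `<Phase1><q>[<Phase2><p>]_(HAFF|nohaff)_<metric>`: first-phase algorithm
#' and its target feature count, optionally a second phase and its target,
#' whether the anti-correlated-pair prefilter ran before the first phase,
#' and the evaluation metric. Examples: `SDA50GA10_HAFF_BACC`,
#' `GA10_nohaff_BACC`, `RFE51_HAFF_BACC`.
#'
#' @param phase1 One of `"SDA"`, `"RFE"`, `"GA"`, `"RND"`, `"HCFR"`,
#'   `"RFECV"`.
#' @param q First-phase target feature count, or `NULL` for selectors whose
#'   count is data-driven.
#' @param phase2 Optional second-phase algorithm (or `NULL`).
#' @param p Second-phase target count (required with `phase2`).
#' @param haff Logical: was the prefilter applied?
#' @param metric Metric token; `"BACC"`.
#' @return Character run name.
#' @export
make_run_name <- function(phase1, q = NULL, phase2 = NULL, p = NULL,
                          haff = FALSE, metric = "BACC") {
  allowed <- c("SDA", "RFE", "GA", "RND", "HCFR", "RFECV")
  if (!phase1 %in% allowed) {
    stop_efs("unknown phase token: ", phase1, class = "parameter_error")
  }
  if (!is.null(phase2) && !phase2 %in% allowed) {
    stop_efs("unknown phase token: ", phase2, class = "parameter_error")
  }
  paste0(phase1, if (!is.null(q)) q,
         if (!is.null(phase2)) paste0(phase2, if (!is.null(p)) p),
         if (isTRUE(haff)) "_HAFF_" else "_nohaff_", metric)
}

#' Describe a selector for the benchmark harness
#'
#' @param family One of `"rnd"`, `"hcfr"`, `"rfe"`, `"rfecv"`, `"sda"`,
#'   `"ga"`, `"sda-ga"`, `"rfe-ga"`.
#' @param p Target feature count (final phase); ignored by `"hcfr"` and
#'   `"rfecv"`, whose counts are data-driven.
#' @param q First-phase target for the dual-phase families.
#' @param haff Apply the anti-correlated-pair prefilter first.
#' @param params Named list of extra arguments for the underlying selector
#'   (e.g. `max_correlation` for hcfr, `gamma` for sda, `population` /
#'   `generations` for the GA families).
#' @return Object of class `selector_spec`.
#' @export
selector_spec <- function(family, p = NULL, q = NULL, haff = FALSE,
                          params = list()) {
  family <- match.arg(family, c("rnd", "hcfr", "rfe", "rfecv", "sda", "ga",
                                "sda-ga", "rfe-ga"))
  if (family %in% c("rnd", "rfe", "sda", "ga", "sda-ga", "rfe-ga") &&
      is.null(p)) {
    stop_efs("family '", family, "' requires p", class = "parameter_error")
  }
  if (family %in% c("sda-ga", "rfe-ga") && is.null(q)) {
    stop_efs("dual-phase families require q", class = "parameter_error")
  }
  structure(list(family = family, p = p, q = q, haff = isTRUE(haff),
                 params = params),
            class = "selector_spec")
}

spec_run_name <- function(spec) {
  token <- c(rnd = "RND", hcfr = "HCFR", rfe = "RFE", rfecv = "RFECV",
             sda = "SDA", ga = "GA", `sda-ga` = "SDA", `rfe-ga` = "RFE")
  phase2 <- if (spec$family %in% c("sda-ga", "rfe-ga")) "GA" else NULL
  q <- if (!is.null(phase2)) spec$q else spec$p
  p2 <- if (!is.null(phase2)) spec$p else NULL
  make_run_name(token[[spec$family]], q = q, phase2 = phase2, p = p2,
                haff = spec$haff)
}

haff_threshold_of <- function(spec) {
  if (!spec$haff) return(NULL)
  thr <- spec$params$haff_threshold
  if (is.null(thr)) 0.95 else thr
}

# Execute one repetition of a selector spec; returns a selection_result.
run_spec_once <- function(spec, table, y, scheme, seed) {
  thr <- haff_threshold_of(spec)
  extra <- spec$params
  extra$haff_threshold <- NULL
  tab <- table
  pre <- NULL
  if (!is.null(thr) && !spec$family %in% c("rfe", "rfecv", "sda-ga", "rfe-ga")) {
    pre <- haff_filter(table, y, threshold = thr)
    tab <- ft_subset(table, pre$selected)
  }
  res <- switch(spec$family,
    rnd = select_random(tab, p = spec$p, seed = seed),
    hcfr = do.call(select_hcfr, c(list(table = tab, seed = seed), extra)),
    rfe = do.call(select_rfe,
      c(list(table = tab, y = y, target_p = spec$p, haff = thr), extra)),
    rfecv = do.call(select_rfe_cv_auto,
      c(list(table = tab, y = y, scheme = scheme, haff = thr), extra)),
    sda = do.call(select_sda,
      c(list(table = tab, y = y, target_p = spec$p, scheme = scheme), extra)),
    ga = do.call(select_ga,
      c(list(table = tab, y = y, target_p = spec$p, seed = seed,
             scheme = scheme), extra)),
    `sda-ga` = dual_phase(tab, y, phase1 = "SDA", q = spec$q, p = spec$p,
                          haff = thr, scheme = scheme, seed = seed,
                          ga_args = extra),
    `rfe-ga` = dual_phase(tab, y, phase1 = "RFE", q = spec$q, p = spec$p,
                          haff = thr, scheme = scheme, seed = seed,
                          ga_args = extra)
  )
  res
}

#' Run the full selector benchmark
#'
#' The evaluation protocol: a baseline linear discriminant is trained per
#' task on all features and scored by cross-validated balanced accuracy;
#' then each selector specification is repeated `repetitions` times per
#' task with repetition seeds `base_seed + i` driving both the selector
#' and the fold split, collecting the held-out balanced accuracy of a
#' classifier refit on the selected features (headline number;
#' resubstitution accuracy is stored alongside) and per-feature selection
#' counts. The whole run is deterministic given (data, config).
#'
#' A failed repetition is recorded with its reason and contributes `NA` to
#' the distribution (denominators in frequency tables always equal the
#' repetition count); if more than 20% of repetitions of any run fail, the
#' benchmark aborts.
#'
#' @param table A [feature_table()].
#' @param labels A [label_set()] aligned to `table`.
#' @param specs List of [selector_spec()]s.
#' @param tasks Character vector of task names (default: all tasks in
#'   `labels`).
#' @param repetitions Repetition count R (default 100).
#' @param cv A [cv_scheme()]; its `k`/`stratified` are used, the seed is
#'   replaced per repetition.
#' @param base_seed Integer base seed.
#' @return Object of class `benchmark_report` with elements
#'   `baseline_bacc`, `distributions`, `resub_distributions`,
#'   `frequency_tables`, `failures`, `repetitions`, `run_names`, `tasks`.
#' @export
run_benchmark <- function(table, labels, specs, tasks = NULL,
                          repetitions = 100L, cv = cv_scheme(),
                          base_seed = 1L) {
  stopifnot(inherits(table, "feature_table"), inherits(labels, "label_set"))
  if (is.null(tasks)) tasks <- names(labels$labels)
  repetitions <- assert_scalar_int(repetitions, "repetitions")
  if (inherits(specs, "selector_spec")) specs <- list(specs)
  catalog <- feature_catalog()

  baseline <- vapply(tasks, function(task) {
    cv_bacc(table, labels$labels[[task]],
            cv_scheme(cv$k, cv$stratified, seed = base_seed))$mean
  }, numeric(1))

  distributions <- list()
  resub <- list()
  freq <- list()
  failures <- list()
  for (spec in specs) {
    run_name <- spec_run_name(spec)
    for (task in tasks) {
      y <- labels$labels[[task]]
      baccs <- rep(NA_real_, repetitions)
      rsub <- rep(NA_real_, repetitions)
      sels <- vector("list", repetitions)
      fails <- character()
      for (i in seq_len(repetitions)) {
        seed_i <- base_seed + i
        scheme_i <- cv_scheme(cv$k, cv$stratified, seed = seed_i)
        out <- tryCatch(
          run_spec_once(spec, table, y, scheme_i, seed_i),
          error = function(e) e
        )
        if (inherits(out, "error")) {
          fails <- c(fails, sprintf("rep %d: %s", i, conditionMessage(out)))
          next
        }
        sels[[i]] <- out$selected
        if (length(out$selected)) {
          sub <- ft_subset(table, out$selected)
          baccs[i] <- cv_bacc(sub, y, scheme_i)$mean
          model <- fit_lda(sub, y)
          rsub[i] <- balanced_accuracy(y, predict(model, sub))
        } else {
          baccs[i] <- 0.5
          rsub[i] <- 0.5
        }
      }
      if (length(fails) > 0.2 * repetitions) {
        stop_efs("run ", run_name, " / ", task, " failed in ",
          length(fails), "/", repetitions, " repetitions: ",
          paste(head(fails, 3L), collapse = "; "),
          class = "benchmark_abort")
      }
      key <- paste(run_name, task, sep = "|")
      distributions[[key]] <- baccs
      resub[[key]] <- rsub
      freq[[key]] <- selection_frequency_table(
        Filter(Negate(is.null), sels), catalog, denominator = repetitions)
      failures[[key]] <- fails
    }
  }
  structure(
    list(baseline_bacc = baseline, distributions = distributions,
         resub_distributions = resub, frequency_tables = freq,
         failures = failures, repetitions = repetitions,
         run_names = vapply(specs, spec_run_name, character(1)),
         tasks = tasks, base_seed = base_seed,
         cv = list(k = cv$k, stratified = cv$stratified)),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report: ", length(x$run_names), " run(s) x ",
      length(x$tasks), " task(s), R = ", x$repetitions, "\n", sep = "")
  cat("baseline BACC: ",
      paste(sprintf("%s=%.3f", names(x$baseline_bacc), x$baseline_bacc),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Selection-frequency table over repetitions
#'
#' Counts, for every feature selected at least once, in how many of the
#' repetitions it appeared, annotated with its catalog class and the
#' coarse shape/intensity/texture type grouping used in reports. Rows are
#' sorted by class and then by descending count; frequencies render as
#' `"numerator/denominator"`.
#'
#' @param results List of [selection_result()]s (or of character vectors of
#'   selected names) from one run.
#' @param catalog Catalog data.frame ([feature_catalog()]); features absent
#'   from it get class `NA`.
#' @param denominator Denominator R; defaults to `length(results)`.
#' @return Data frame with columns `feature_name`, `feature_class`,
#'   `type_group`, `frequency_numerator`, `frequency_denominator`,
#'   `frequency`.
#' @export
selection_frequency_table <- function(results, catalog = feature_catalog(),
                                      denominator = length(results)) {
  sels <- lapply(results, function(r) {
    if (inherits(r, "selection_result")) r$selected else as.character(r)
  })
  if (!length(sels)) {
    return(data.frame(feature_name = character(),
                      feature_class = character(),
                      type_group = character(),
                      frequency_numerator = integer(),
                      frequency_denominator = integer(),
                      frequency = character(),
                      stringsAsFactors = FALSE))
  }
  counts <- table(unlist(sels))
  df <- data.frame(feature_name = names(counts),
                   frequency_numerator = as.integer(counts),
                   stringsAsFactors = FALSE)
  m <- match(df$feature_name, catalog$name)
  df$feature_class <- as.character(catalog$feature_class[m])
  df$type_group <- ifelse(is.na(m), NA_character_,
                          catalog_type_group(df$feature_class))
  df$frequency_denominator <- as.integer(denominator)
  df$frequency <- sprintf("%d/%d", df$frequency_numerator,
                          df$frequency_denominator)
  cls <- factor(df$feature_class, levels = levels(catalog$feature_class))
  df <- df[order(cls, -df$frequency_numerator, df$feature_name), ]
  rownames(df) <- NULL
  df[, c("feature_name", "feature_class", "type_group",
         "frequency_numerator", "frequency_denominator", "frequency")]
}

#' Summarise benchmark BACC distributions
#'
#' Per (run, task): min, quartiles, max and mean of the balanced-accuracy
#' distribution, with the task's baseline accuracy attached as the
#' reference value for boxplot overlays.
#'
#' @param report A `benchmark_report`.
#' @return Data frame with one row per (run_name, task).
#' @export
summarize_distributions <- function(report) {
  stopifnot(inherits(report, "benchmark_report"))
  keys <- names(report$distributions)
  rows <- lapply(keys, function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    v <- report$distributions[[key]]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE,
                         names = FALSE)
    data.frame(run_name = parts[1L], task = parts[2L],
               min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L],
               max = q[5L], mean = mean(v, na.rm = TRUE),
               n_failed = sum(is.na(v)),
               baseline = unname(report$baseline_bacc[parts[2L]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Boxplot of benchmark BACC distributions
#'
#' One box per run, faceted by task, with the baseline accuracy drawn as a
#' dash-dotted horizontal reference line. Requires ggplot2.
#'
#' @param report A `benchmark_report`.
#' @return A ggplot object.
#' @export
plot_bacc_distributions <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_efs("ggplot2 is required for plotting", class = "parameter_error")
  }
  keys <- names(report$distributions)
  df <- do.call(rbind, lapply(keys, function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    data.frame(run_name = parts[1L], task = parts[2L],
               bacc = report$distributions[[key]],
               stringsAsFactors = FALSE)
  }))
  base <- data.frame(task = names(report$baseline_bacc),
                     baseline = unname(report$baseline_bacc))
  ggplot2::ggplot(df, ggplot2::aes(x = run_name, y = bacc)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(data = base,
      ggplot2::aes(yintercept = baseline),
      linetype = "dotdash", colour = "darkgreen") +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = NULL, y = "balanced accuracy") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Write a benchmark report to a directory
#'
#' Persists the report as JSON (full per-run distributions and frequency
#' tables) plus two CSVs: the distribution summary and the concatenated
#' frequency tables. Writing then re-reading the JSON reproduces the
#' report's numbers exactly.
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- unclass(report)
  payload$baseline_bacc <- as.list(payload$baseline_bacc)
  # I(17) significant digits keeps doubles bit-exact through the round-trip
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       dataframe = "columns")
  write.csv(summarize_distributions(report),
            file.path(dir, "summary.csv"), row.names = FALSE)
  freq <- do.call(rbind, lapply(names(report$frequency_tables), function(key) {
    ft <- report$frequency_tables[[key]]
    if (!nrow(ft)) return(NULL)
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    cbind(data.frame(run_name = parts[1L], task = parts[2L],
                     stringsAsFactors = FALSE), ft)
  }))
  if (is.null(freq)) freq <- data.frame()
  write.csv(freq, file.path(dir, "selection_frequencies.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a persisted benchmark report
#'
#' @param dir Directory written by [write_report()].
#' @return A `benchmark_report`.
#' @export
read_report <- function(dir) {
  payload <- jsonlite::read_json(file.path(dir, "report.json"),
                                 simplifyVector = TRUE)
  payload$distributions <- lapply(payload$distributions, as.numeric)
  payload$resub_distributions <- lapply(payload$resub_distributions,
                                        as.numeric)
  payload$frequency_tables <- lapply(payload$frequency_tables,
                                     as.data.frame)
  payload$baseline_bacc <- unlist(payload$baseline_bacc)
  payload$failures <- lapply(payload$failures, as.character)
  structure(payload, class = "benchmark_report")
}
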