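#' Construct a feature table
#'
#' A feature table is the package's container for a wide radiomic matrix:
#' one row per segmented lesion, one column per feature. Values must be
#' finite; missing values are a hard error (no imputation is performed).
#'
#' @param values Numeric matrix (n x d) or data.frame of feature values.
#' @param sample_ids Character vector of n unique sample identifiers; taken
#'   from rownames when `NULL`. Sample ids are opaque strings.
#' @param feature_names Character vector of d unique feature names; taken
#'   from colnames when `NULL`.
#' @return An object of class `feature_table`: a list with elements
#'   `values` (numeric matrix with dimnames), `sample_ids`, `feature_names`.
#' @export
feature_table <- function(values, sample_ids = NULL, feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) {
    stop_efs("feature names are required", class = "validation_error")
  }
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(values)) {
    stop_efs("feature_names length does not match column count",
      class = "validation_error")
  }
  if (length(sample_ids) != nrow(values)) {
    stop_efs("sample_ids length does not match row count",
      class = "validation_error")
  }
  if (anyDuplicated(feature_names)) {
    stop_efs("duplicate feature names: ",
      paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "),
      class = "validation_error")
  }
  if (anyDuplicated(sample_ids)) {
    stop_efs("duplicate sample ids", class = "validation_error")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_efs("non-finite value at row ", bad[1L], " (", sample_ids[bad[1L]],
      "), column ", bad[2L], " (", feature_names[bad[2L]], ")",
      class = "validation_error")
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, sample_ids = sample_ids,
         feature_names = feature_names),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# Subset a feature table by feature name (keeps all rows).
ft_subset <- function(table, features) {
  feature_table(table$values[, features, drop = FALSE],
                sample_ids = table$sample_ids, feature_names = features)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a wide-format feature table from CSV/TSV
#'
#' Reads a delimited table with one row per segmented lesion and a header of
#' feature names. Columns whose name starts with `diagnostics_` (extractor
#' metadata) are dropped. A column named `sample_id` (or the first column if
#' it is non-numeric) supplies sample identifiers. The delimiter is
#' auto-detected (comma or tab).
#'
#' @param path Path to the CSV/TSV file.
#' @param catalog Catalog data.frame as returned by [feature_catalog()];
#'   used for validation/ordering. `NULL` skips catalog checks.
#' @param strict When `TRUE` (and a catalog is given) the retained columns
#'   must cover the full catalog; they are returned in catalog order and a
#'   missing catalog column is an error naming the column.
#' @return A [feature_table()].
#' @export
load_feature_table <- function(path, catalog = NULL, strict = FALSE) {
  sep <- detect_sep(path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (ncol(df) == 0L) stop_efs("empty table: ", path, class = "parse_error")
  nm <- names(df)
  ids <- NULL
  if ("sample_id" %in% nm) {
    ids <- as.character(df[["sample_id"]])
    df <- df[, setdiff(nm, "sample_id"), drop = FALSE]
  } else if (is.character(df[[1L]])) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  keep <- !startsWith(names(df), "diagnostics_")
  df <- df[, keep, drop = FALSE]
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop_efs("non-numeric value at row ", bad[1L], ", column '",
          names(df)[j], "'", class = "parse_error")
      }
      df[[j]] <- num
    }
  }
  if (!is.null(catalog)) {
    missing <- setdiff(catalog$name, names(df))
    if (strict) {
      if (length(missing)) {
        stop_efs("missing catalog column(s): ",
          paste(missing, collapse = ", "), class = "validation_error")
      }
      df <- df[, catalog$name, drop = FALSE]
    }
  }
  feature_table(as.matrix(df), sample_ids = ids)
}

#' Write a feature table to CSV
#'
#' Round-trips through [load_feature_table()]: names, ids and finite values
#' are reproduced exactly (values are written with full precision).
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(table$values)
  names(vals) <- table$feature_names
  df <- cbind(df, vals)
  # format() at 17 significant digits preserves doubles bit-exactly
  for (j in seq(2L, ncol(df))) {
    df[[j]] <- format(df[[j]], digits = 17, scientific = TRUE, trim = TRUE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a label set
#'
#' Per-sample binary labels for up to three classification tasks:
#' `pathologic`, `pathologic_with_ECS` and `non_pathologic`. Extracapsular
#' spread (ECS) is by definition nested inside the pathologic class, so
#' every sample with `pathologic_with_ECS = 1` must also carry
#' `pathologic = 1`.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param labels Named list of 0/1 integer vectors, one per task.
#' @return An object of class `label_set`.
#' @export
label_set <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  labels <- lapply(labels, function(v) {
    v <- as.integer(v)
    if (length(v) != n || anyNA(v) || !all(v %in% c(0L, 1L))) {
      stop_efs("labels must be 0/1 vectors of length ", n,
        class = "validation_error")
    }
    v
  })
  for (task in names(labels)) {
    if (length(unique(labels[[task]])) < 2L) {
      stop_efs("task '", task, "' has a single class",
        class = "degenerate_label_error")
    }
  }
  if (all(c("pathologic", "pathologic_with_ECS") %in% names(labels))) {
    viol <- labels$pathologic_with_ECS == 1L & labels$pathologic == 0L
    if (any(viol)) {
      stop_efs("ECS=1 with pathologic=0 for sample(s): ",
        paste(sample_ids[viol], collapse = ", "),
        class = "consistency_error")
    }
  }
  structure(list(sample_ids = sample_ids, labels = labels),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("label_set: ", length(x$sample_ids), " samples; tasks: ",
      paste(sprintf("%s (%d pos)", names(x$labels),
                    vapply(x$labels, sum, integer(1))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read task labels and align them to a feature table
#'
#' Expects a delimited file with a `sample_id` column and one 0/1 column per
#' task. Rows are re-ordered to match the feature table; an id absent from
#' the table is an alignment error.
#'
#' @param path Path to the label CSV.
#' @param table The companion [feature_table()].
#' @return A [label_set()] row-aligned to `table`.
#' @export
load_labels <- function(path, table) {
  sep <- detect_sep(path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop_efs("label file must contain a sample_id column",
      class = "parse_error")
  }
  ids <- as.character(df$sample_id)
  unknown <- setdiff(ids, table$sample_ids)
  if (length(unknown)) {
    stop_efs("label sample id(s) not present in feature table: ",
      paste(head(unknown, 5L), collapse = ", "), class = "alignment_error")
  }
  if (!setequal(ids, table$sample_ids)) {
    stop_efs("labels do not cover all feature-table samples",
      class = "alignment_error")
  }
  df <- df[match(table$sample_ids, ids), , drop = FALSE]
  tasks <- setdiff(names(df), "sample_id")
  label_set(table$sample_ids, as.list(df[tasks]))
}

#' Write a label set to CSV
#' @param labels A [label_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample_id = labels$sample_ids, stringsAsFactors = FALSE)
  for (task in names(labels$labels)) df[[task]] <- labels$labels[[task]]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
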