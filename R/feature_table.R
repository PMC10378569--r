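#' Construct a feature table
#'
#' A `feature_table` holds a samples-by-features numeric matrix (missing
#' values allowed as `NA`), a categorical class label per sample, and
#' optional sample identifiers. It is the raw-data container that all
#' preprocessing, discretization and benchmarking functions operate on.
#'
#' @param values Numeric matrix or data frame, one row per sample, one column
#'   per feature. Column names are used as feature names; unnamed columns get
#'   `V1, V2, ...`.
#' @param class_labels Vector of class labels, one per sample. Treated as
#'   opaque categories (no ordering assumed); may not contain `NA`.
#' @param sample_ids Optional character vector of sample identifiers.
#' @return An object of class `feature_table` with components `values`
#'   (numeric matrix), `feature_names`, `class_labels` (character) and
#'   `sample_ids` (character or `NULL`).
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2,
#'                            dimnames = list(NULL, c("p1", "p2"))),
#'                     rep(c("A", "B"), 5))
#' missing_fraction(ft)
#' @export
feature_table <- function(values, class_labels, sample_ids = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix or data frame", call. = FALSE)
  if (is.null(colnames(values)) && ncol(values) > 0)
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (length(class_labels) != nrow(values))
    stop("`class_labels` must have one entry per row of `values`",
         call. = FALSE)
  if (anyNA(class_labels))
    stop("missing class labels are not allowed", call. = FALSE)
  if (!is.null(sample_ids) && length(sample_ids) != nrow(values))
    stop("`sample_ids` must have one entry per row", call. = FALSE)
  structure(
    list(values = values,
         feature_names = colnames(values) %||% character(),
         class_labels = as.character(class_labels),
         sample_ids = if (!is.null(sample_ids)) as.character(sample_ids)),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features, %d classes\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$class_labels))))
  mf <- missing_fraction(x)
  if (any(mf > 0))
    cat(sprintf("  %d feature(s) with missing values (max fraction %.3f)\n",
                sum(mf > 0), max(mf)))
  dropped <- attr(x, "dropped_features")
  if (!is.null(dropped) && length(dropped))
    cat("  dropped by missing-value filter:",
        paste(dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read a delimited feature table
#'
#' Reads a header-bearing delimited text file (CSV/TSV) with one row per
#' sample, extracts the class column, and parses the remaining columns as
#' numeric features. Cells equal to `na_token` become missing values.
#'
#' @param path Path to the input file.
#' @param target_column Name of the column holding the class labels.
#' @param delimiter Field delimiter (default `","`; use `"\t"` for TSV).
#' @param na_token Text marking a missing cell (default `"NA"`).
#' @param id_column Optional name of a sample-identifier column.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, target_column, delimiter = ",",
                               na_token = "NA", id_column = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "\"",
                           comment.char = "")
  if (anyDuplicated(names(raw)))
    stop("duplicate feature names in header: ",
         paste(unique(names(raw)[duplicated(names(raw))]),
               collapse = ", "), call. = FALSE)
  if (!target_column %in% names(raw))
    stop(sprintf("target column \"%s\" not found (columns: %s)",
                 target_column, paste(names(raw), collapse = ", ")),
         call. = FALSE)
  labels <- raw[[target_column]]
  if (any(labels == na_token))
    stop("missing class label (\"", na_token, "\") in row(s) ",
         paste(which(labels == na_token), collapse = ", "), call. = FALSE)
  ids <- NULL
  drop_cols <- target_column
  if (!is.null(id_column)) {
    if (!id_column %in% names(raw))
      stop(sprintf("id column \"%s\" not found", id_column), call. = FALSE)
    ids <- raw[[id_column]]
    drop_cols <- c(drop_cols, id_column)
  }
  feats <- raw[!(names(raw) %in% drop_cols)]
  vals <- matrix(NA_real_, nrow(raw), length(feats),
                 dimnames = list(NULL, names(feats)))
  for (j in seq_along(feats)) {
    cell <- feats[[j]]
    is_na <- cell == na_token
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_na & is.na(num))
    if (length(bad))
      stop(sprintf(
        "non-numeric value \"%s\" in column \"%s\", row %d",
        cell[bad[1]], names(feats)[j], bad[1]), call. = FALSE)
    num[is_na] <- NA_real_
    vals[, j] <- num
  }
  feature_table(vals, labels, ids)
}

#' Write a feature table to delimited text
#'
#' Inverse of [read_feature_table()]: writes features plus the class column
#' (and sample ids, when present) with full numeric precision, so a complete
#' table round-trips exactly through the text format.
#'
#' @param table A [feature_table].
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @param na_token Text to write for missing cells.
#' @param target_column Name for the class column in the output.
#' @export
write_feature_table <- function(table, path, delimiter = ",",
                                na_token = "NA", target_column = "class") {
  stopifnot(inherits(table, "feature_table"))
  if (target_column %in% table$feature_names)
    stop("target column name collides with a feature name", call. = FALSE)
  df <- as.data.frame(table$values)
  # format full precision, avoiding scientific-vs-fixed round-trip surprises
  for (j in seq_along(df)) df[[j]] <- sprintf("%.17g", df[[j]])
  df[df == "nan" | df == "NA"] <- na_token
  df[[target_column]] <- table$class_labels
  if (!is.null(table$sample_ids)) df <- cbind(sample_id = table$sample_ids, df)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = na_token)
  invisible(path)
}

#' Per-feature missing-value fraction
#'
#' @param table A [feature_table].
#' @return Named numeric vector, the fraction of missing cells per feature.
#' @export
missing_fraction <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  colMeans(is.na(table$values))
}

#' Drop features with too many missing values
#'
#' Retains exactly the features whose missing fraction is less than or equal
#' to `max_missing_fraction`; features with a strictly greater fraction are
#' dropped (a feature missing in exactly half the samples survives the
#' default 0.5 threshold). Column order is preserved. The names of dropped
#' features are attached as attribute `"dropped_features"` and available via
#' [dropped_features()].
#'
#' @param table A [feature_table].
#' @param max_missing_fraction Threshold in `[0, 1]`; default `0.5`.
#' @return A filtered [feature_table] (possibly with zero features).
#' @export
filter_missing <- function(table, max_missing_fraction = 0.5) {
  stopifnot(inherits(table, "feature_table"),
            is.numeric(max_missing_fraction),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  mf <- missing_fraction(table)
  keep <- mf <= max_missing_fraction
  out <- feature_table(table$values[, keep, drop = FALSE],
                       table$class_labels, table$sample_ids)
  attr(out, "dropped_features") <- table$feature_names[!keep]
  out
}

#' Names of features removed by the missing-value filter
#'
#' @param table A [feature_table] returned by [filter_missing()].
#' @return Character vector (empty when nothing was dropped).
#' @export
dropped_features <- function(table) {
  d <- attr(table, "dropped_features")
  if (is.null(d)) character() else d
}

#' Mean-impute missing values
#'
#' Replaces each missing cell by the arithmetic mean of the observed values
#' of the same feature. Every feature must have at least one observed value.
#'
#' @param table A [feature_table].
#' @return A complete [feature_table] (no missing cells).
#' @export
impute_mean <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (!any(miss)) next
    if (all(miss))
      stop("feature \"", table$feature_names[j],
           "\" has no observed values to impute from", call. = FALSE)
    vals[miss, j] <- mean(vals[!miss, j])
  }
  out <- feature_table(vals, table$class_labels, table$sample_ids)
  attr(out, "dropped_features") <- attr(table, "dropped_features")
  out
}
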