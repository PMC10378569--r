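#' Fit an equal-width binning model
#'
#' For each feature, spans the observed range `[min, max]` with `bins`
#' equal-width intervals. A constant feature yields a degenerate single-bin
#' model. The standard protocol for continuous benchmark data uses 5 bins;
#' 3 bins is the convention for expression-type data.
#'
#' @param table A complete [feature_table] (no missing cells; run
#'   [filter_missing()] and [impute_mean()] first).
#' @param bins Positive integer number of bins per feature.
#' @return An object of class `binning_model`: per-feature `lower`, `upper`,
#'   `bins`, and the derived `edges` list (length `bins + 1` per feature,
#'   evenly spaced).
#' @export
fit_equal_width <- function(table, bins) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(bins) || length(bins) != 1L || bins < 1 || bins != round(bins))
    stop("`bins` must be a single positive integer", call. = FALSE)
  if (anyNA(table$values))
    stop("table has missing cells; impute or filter before binning",
         call. = FALSE)
  bins <- as.integer(bins)
  lower <- unname(apply(table$values, 2, min))
  upper <- unname(apply(table$values, 2, max))
  edges <- lapply(seq_along(lower), function(j) {
    if (upper[j] == lower[j]) c(lower[j], upper[j])  # degenerate single bin
    else seq(lower[j], upper[j], length.out = bins + 1L)
  })
  names(edges) <- table$feature_names
  structure(list(feature_names = table$feature_names,
                 lower = lower, upper = upper,
                 bins = bins, edges = edges),
            class = "binning_model")
}

#' @export
print.binning_model <- function(x, ...) {
  cat(sprintf("binning_model: %d features, %d equal-width bins\n",
              length(x$feature_names), x$bins))
  invisible(x)
}

#' Construct a discrete table from integer codes
#'
#' Low-level constructor for already-coded data (e.g. the output of
#' [apply_binning()], or hand-built fixtures). Codes are nonnegative
#' integers; the class is coded `0 .. c-1`.
#'
#' @param codes Integer matrix, samples by features, nonnegative codes.
#' @param class_codes Integer vector of class codes (or any vector, which is
#'   coded by first appearance).
#' @param feature_names Optional feature names (default: column names).
#' @return An object of class `discrete_table` with components `codes`,
#'   `arities` (distinct observed codes per feature), `class_codes`,
#'   `n_classes` and `feature_names`.
#' @export
discrete_table <- function(codes, class_codes, feature_names = NULL) {
  if (is.data.frame(codes)) codes <- as.matrix(codes)
  if (!is.matrix(codes)) stop("`codes` must be a matrix", call. = FALSE)
  storage.mode(codes) <- "integer"
  if (anyNA(codes)) stop("`codes` may not contain NA", call. = FALSE)
  if (any(codes < 0L)) stop("codes must be nonnegative", call. = FALSE)
  if (length(class_codes) != nrow(codes))
    stop("`class_codes` must have one entry per row", call. = FALSE)
  if (is.null(feature_names))
    feature_names <- colnames(codes)
  if (is.null(feature_names))
    feature_names <- paste0("V", seq_len(ncol(codes)))
  colnames(codes) <- feature_names
  cc <- match(class_codes, unique(class_codes)) - 1L
  structure(
    list(codes = codes,
         arities = apply(codes, 2, function(v) length(unique(v))),
         class_codes = cc,
         class_levels = as.character(unique(class_codes)),
         n_classes = length(unique(cc)),
         feature_names = feature_names),
    class = "discrete_table")
}

#' @export
print.discrete_table <- function(x, ...) {
  cat(sprintf(
    "discrete_table: %d samples x %d features, %d classes, arities %s\n",
    nrow(x$codes), ncol(x$codes), x$n_classes,
    paste(range(x$arities), collapse = "-")))
  invisible(x)
}

#' Apply a binning model to a feature table
#'
#' Maps each value to the bin whose half-open interval `[e_k, e_{k+1})`
#' contains it; the upper boundary of the last bin is inclusive, so the
#' fitted maximum lands in the top bin. Values outside the fitted range
#' (possible when the model was fit on a training split) clip to the nearest
#' extreme bin. Class labels are integer-coded by first appearance order.
#'
#' @param table A complete [feature_table] whose features all appear in
#'   `model`.
#' @param model A [fit_equal_width()] model.
#' @return A [discrete_table] with codes in `0 .. bins-1`.
#' @export
apply_binning <- function(table, model) {
  stopifnot(inherits(table, "feature_table"),
            inherits(model, "binning_model"))
  if (anyNA(table$values))
    stop("table has missing cells; impute or filter before binning",
         call. = FALSE)
  absent <- setdiff(table$feature_names, model$feature_names)
  if (length(absent))
    stop("features absent from binning model: ",
         paste(absent, collapse = ", "), call. = FALSE)
  codes <- matrix(0L, nrow(table$values), ncol(table$values),
                  dimnames = list(NULL, table$feature_names))
  for (j in seq_len(ncol(codes))) {
    e <- model$edges[[table$feature_names[j]]]
    if (length(e) == 2L && e[1] == e[2]) next  # degenerate: all code 0
    # half-open bins, max inclusive, out-of-range clipped to extreme bins
    codes[, j] <- findInterval(table$values[, j], e,
                               rightmost.closed = TRUE,
                               all.inside = TRUE) - 1L
  }
  discrete_table(codes, table$class_labels, table$feature_names)
}

#' Discretize in one step
#'
#' Convenience wrapper: [fit_equal_width()] then [apply_binning()] on the
#' same table.
#'
#' @inheritParams fit_equal_width
#' @return A [discrete_table].
#' @export
discretize_table <- function(table, bins) {
  apply_binning(table, fit_equal_width(table, bins))
}

#' Per-feature arities and their median
#'
#' The arity of a feature is the number of distinct observed codes. The
#' median arity enters the dataset difficulty ratio `N / (m * c)` (see
#' [dataset_ratio()]).
#'
#' @param discrete A [discrete_table].
#' @return List with `arities` (named integer vector) and `median_arity`
#'   (standard even/odd median).
#' @export
arity_stats <- function(discrete) {
  stopifnot(inherits(discrete, "discrete_table"))
  list(arities = discrete$arities,
       median_arity = stats::median(discrete$arities))
}
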