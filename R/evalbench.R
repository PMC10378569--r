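# Stratified cross-validation benchmarking of criterion + classifier pairs,
# the dataset-difficulty ratio, and the paired-t Win/Tie/Loss comparison.

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin from a rotating start, so per-fold class counts differ
# from proportionality by at most one sample.
.stratified_folds <- function(labels, folds) {
  n <- length(labels)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  if (min(table(labels)) < 1L) stop("empty class", call. = FALSE)
  assign <- integer(n)
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
    offset <- (offset + length(idx)) %% folds
  }
  lapply(seq_len(folds), function(f) which(assign == f))
}

.rows <- function(table, idx) {
  feature_table(table$values[idx, , drop = FALSE],
                table$class_labels[idx],
                if (!is.null(table$sample_ids)) table$sample_ids[idx])
}

#' Cross-validated accuracy of a criterion + classifier pair
#'
#' Runs stratified `folds`-fold cross-validation: in each fold the held-out
#' samples are set aside, the remaining samples are discretized (bin edges
#' fit on the training portion by default, or on the full table for
#' replication of protocols that discretize up front), the selection
#' criterion is run on the training portion, the classifier is trained on
#' the top-`K` features and scored on the held-out fold.
#'
#' The classifier sees the representation its adapter declares: discrete
#' codes (e.g. naive Bayes) or the original continuous values (e.g. KNN,
#' SVM). With a fixed `seed` the report is identical across runs.
#'
#' @param data A complete [feature_table].
#' @param criterion A [criterion_spec()] or criterion name.
#' @param classifier A classifier adapter ([classifier_knn()] etc.) or one
#'   of `"knn"`, `"nbc"`, `"svm"`, `"majority"`.
#' @param K Number of features to keep (protocol default 15).
#' @param folds Number of folds (protocol default 10, i.e. 90/10 splits).
#' @param bins Equal-width bin count for discretization (default 5).
#' @param seed Integer seed controlling the fold partition.
#' @param fit_bins_on `"train"` (leakage-safe default) or `"full"`
#'   (discretize the whole table up front).
#' @param select_on `"train"` (default: rank features inside each training
#'   fold) or `"full"` (rank once on the whole table).
#' @return An object of class `cv_report`: per-fold accuracies, their mean
#'   and standard deviation, and the run parameters.
#' @export
evaluate_cv <- function(data, criterion, classifier, K = 15, folds = 10,
                        bins = 5, seed = 1,
                        fit_bins_on = c("train", "full"),
                        select_on = c("train", "full")) {
  stopifnot(inherits(data, "feature_table"))
  if (is.character(criterion)) criterion <- criterion_spec(criterion)
  classifier <- .resolve_classifier(classifier)
  fit_bins_on <- match.arg(fit_bins_on)
  select_on <- match.arg(select_on)
  if (K > ncol(data$values))
    stop("K exceeds the number of features", call. = FALSE)
  if (anyNA(data$values))
    stop("table has missing cells; preprocess first", call. = FALSE)

  set.seed(seed)
  fold_idx <- .stratified_folds(data$class_labels, folds)

  full_model <- if (fit_bins_on == "full") fit_equal_width(data, bins)
  full_trace <- if (select_on == "full") {
    model0 <- if (is.null(full_model)) fit_equal_width(data, bins) else full_model
    select_features(apply_binning(data, model0), criterion, K)
  }

  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold_idx[[f]]
    tr <- setdiff(seq_len(nrow(data$values)), te)
    train_tab <- .rows(data, tr)
    test_tab <- .rows(data, te)
    model <- if (fit_bins_on == "full") full_model
             else fit_equal_width(train_tab, bins)
    dtr <- apply_binning(train_tab, model)
    feats <- if (select_on == "full") full_trace$selected
             else select_features(dtr, criterion, K)$selected
    if (classifier$representation == "discrete") {
      dte <- apply_binning(test_tab, model)
      xtr <- dtr$codes[, feats, drop = FALSE]
      xte <- dte$codes[, feats, drop = FALSE]
    } else {
      xtr <- train_tab$values[, feats, drop = FALSE]
      xte <- test_tab$values[, feats, drop = FALSE]
    }
    fit <- tryCatch(classifier$train(xtr, train_tab$class_labels),
                    error = function(e)
                      stop("classifier \"", classifier$name,
                           "\" failed in fold ", f, ": ",
                           conditionMessage(e), call. = FALSE))
    pred <- classifier$predict(fit, xte)
    acc[f] <- mean(pred == test_tab$class_labels)
  }
  structure(
    list(method = criterion$name, classifier = classifier$name, K = K,
         folds = folds, bins = bins, seed = seed,
         fit_bins_on = fit_bins_on, select_on = select_on,
         accuracies = acc, mean = mean(acc), sd = stats::sd(acc)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %s + %s, K=%d, %d folds: %.2f%% +/- %.2f\n",
              x$method, x$classifier, x$K, x$folds,
              100 * x$mean, 100 * x$sd))
  invisible(x)
}

#' Accuracy as a function of the number of selected features
#'
#' For each fold, features are ranked once on the training portion up to
#' `k_max`; for every `k` in `1..k_max` each classifier is trained on the
#' top-`k` prefix and scored on the held-out fold. The curve is the per-`k`
#' accuracy averaged over folds and classifiers.
#'
#' @inheritParams evaluate_cv
#' @param classifiers List of classifier adapters (or names) to average
#'   over.
#' @param k_max Largest prefix length (default 30).
#' @return An object of class `accuracy_curve`: `k`, `mean_accuracy`
#'   (length `k_max`), and the per-classifier accuracy matrix.
#' @export
accuracy_curve <- function(data, criterion, classifiers = list("knn"),
                           k_max = 30, folds = 10, bins = 5, seed = 1,
                           fit_bins_on = c("train", "full")) {
  stopifnot(inherits(data, "feature_table"))
  if (is.character(criterion)) criterion <- criterion_spec(criterion)
  fit_bins_on <- match.arg(fit_bins_on)
  if (!is.list(classifiers)) classifiers <- as.list(classifiers)
  classifiers <- lapply(classifiers, .resolve_classifier)
  if (k_max > ncol(data$values))
    stop("k_max exceeds the number of features", call. = FALSE)

  set.seed(seed)
  fold_idx <- .stratified_folds(data$class_labels, folds)
  full_model <- if (fit_bins_on == "full") fit_equal_width(data, bins)

  per_cl <- matrix(0, k_max, length(classifiers),
                   dimnames = list(NULL, vapply(classifiers, `[[`,
                                                character(1), "name")))
  for (f in seq_len(folds)) {
    te <- fold_idx[[f]]
    tr <- setdiff(seq_len(nrow(data$values)), te)
    train_tab <- .rows(data, tr)
    test_tab <- .rows(data, te)
    model <- if (fit_bins_on == "full") full_model
             else fit_equal_width(train_tab, bins)
    dtr <- apply_binning(train_tab, model)
    dte <- apply_binning(test_tab, model)
    ranking <- select_features(dtr, criterion, k_max)$selected
    for (ci in seq_along(classifiers)) {
      cl <- classifiers[[ci]]
      for (k in seq_len(k_max)) {
        feats <- ranking[seq_len(k)]
        if (cl$representation == "discrete") {
          xtr <- dtr$codes[, feats, drop = FALSE]
          xte <- dte$codes[, feats, drop = FALSE]
        } else {
          xtr <- train_tab$values[, feats, drop = FALSE]
          xte <- test_tab$values[, feats, drop = FALSE]
        }
        fit <- cl$train(xtr, train_tab$class_labels)
        per_cl[k, ci] <- per_cl[k, ci] +
          mean(cl$predict(fit, xte) == test_tab$class_labels)
      }
    }
  }
  per_cl <- per_cl / folds
  structure(list(k = seq_len(k_max),
                 mean_accuracy = rowMeans(per_cl),
                 per_classifier = per_cl,
                 method = criterion$name, folds = folds, seed = seed),
            class = "accuracy_curve")
}

#' @export
as.data.frame.accuracy_curve <- function(x, ...) {
  data.frame(k = x$k, mean_accuracy = x$mean_accuracy)
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("accuracy_curve (%s): k = 1..%d, max %.2f%% at k = %d\n",
              x$method, max(x$k), 100 * max(x$mean_accuracy),
              which.max(x$mean_accuracy)))
  invisible(x)
}

#' Dataset difficulty ratio
#'
#' `round(N / (m * c))` where `N` is the sample count, `m` the median
#' feature arity and `c` the class count; rounding is half away from zero.
#' Smaller ratios mean fewer samples per (arity, class) cell and a harder
#' selection problem.
#'
#' @param N Number of samples.
#' @param median_arity Median feature arity (equals the bin count for
#'   equal-width-discretized continuous data).
#' @param c Number of classes.
#' @return Integer ratio.
#' @examples
#' dataset_ratio(5000, 5, 3)  # 333
#' dataset_ratio(6598, 5, 2)  # 660 (659.8 rounds up)
#' @export
dataset_ratio <- function(N, median_arity, c) {
  stopifnot(is.numeric(N), is.numeric(median_arity), is.numeric(c))
  if (N <= 0 || median_arity <= 0 || c <= 0)
    stop("all arguments must be positive", call. = FALSE)
  x <- N / (median_arity * c)
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Win/Tie/Loss comparison of two cross-validation reports
#'
#' Paired two-sided t-test on the per-fold accuracy differences of two
#' matched [evaluate_cv()] runs. From the reference method's perspective:
#' Win when its mean is higher and the difference is significant at `alpha`,
#' Loss when lower and significant, Tie otherwise. Identical (zero-variance
#' difference) vectors are a Tie, with an undefined p-value reported as
#' `NA`.
#'
#' @param reference,baseline `cv_report`s with equal fold counts from
#'   matched partitions (same seed).
#' @param alpha Significance level (protocol default 0.1).
#' @param paired Use the paired test (default); set `FALSE` for the
#'   two-sample (Welch) variant.
#' @return An object of class `wtl_comparison`: `decision` in
#'   `c("Win", "Tie", "Loss")`, `p_value`, `mean_diff`, `alpha`.
#' @export
compare_wtl <- function(reference, baseline, alpha = 0.1, paired = TRUE) {
  stopifnot(inherits(reference, "cv_report"), inherits(baseline, "cv_report"))
  a <- reference$accuracies
  b <- baseline$accuracies
  if (length(a) != length(b))
    stop("reports have different numbers of folds", call. = FALSE)
  d <- a - b
  if (isTRUE(all.equal(stats::sd(d), 0)) || all(d == 0)) {
    p <- NA_real_
    decision <- "Tie"
  } else {
    p <- if (paired) stats::t.test(a, b, paired = TRUE)$p.value
         else stats::t.test(a, b)$p.value
    decision <- if (p < alpha && mean(d) > 0) "Win"
                else if (p < alpha && mean(d) < 0) "Loss"
                else "Tie"
  }
  structure(list(decision = decision, p_value = p,
                 mean_diff = mean(d), alpha = alpha,
                 reference = reference$method, baseline = baseline$method),
            class = "wtl_comparison")
}

#' @export
print.wtl_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: %s (p = %s, mean diff = %+.4f, alpha = %g)\n",
              x$reference, x$baseline, x$decision,
              format(x$p_value, digits = 3), x$mean_diff, x$alpha))
  invisible(x)
}
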