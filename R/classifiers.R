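# Classifier adapters: a plain list with `name`, `representation`
# ("original" continuous values or "discrete" codes), and two closures,
# train(x, y) -> model and predict(model, x) -> labels. The benchmarking
# protocol only relies on this contract, so any classifier can be plugged in.

.new_classifier <- function(name, representation, train, predict) {
  structure(list(name = name, representation = representation,
                 train = train, predict = predict),
            class = "wbfs_classifier")
}

#' @export
print.wbfs_classifier <- function(x, ...) {
  cat("classifier adapter:", x$name, sprintf("(%s features)\n",
                                             x$representation))
  invisible(x)
}

#' k-nearest-neighbour classifier adapter
#'
#' Wraps [class::knn()]; operates on the original (continuous) feature
#' values. The protocol default is `k = 5`.
#'
#' @param k Number of neighbours.
#' @return A classifier adapter for [evaluate_cv()].
#' @export
classifier_knn <- function(k = 5) {
  .new_classifier(
    sprintf("knn%d", k), "original",
    train = function(x, y) list(x = as.matrix(x), y = factor(y), k = k),
    predict = function(model, x) {
      k_eff <- min(model$k, nrow(model$x))
      as.character(class::knn(model$x, as.matrix(x), model$y, k = k_eff))
    })
}

#' Naive Bayes classifier adapter
#'
#' Wraps [e1071::naiveBayes()] on the discretized codes (each feature a
#' factor), the natural representation for a categorical naive Bayes model.
#'
#' @param laplace Additive smoothing passed through to [e1071::naiveBayes()].
#' @return A classifier adapter for [evaluate_cv()].
#' @export
classifier_nbc <- function(laplace = 1) {
  as_factors <- function(x) as.data.frame(lapply(as.data.frame(x), factor))
  .new_classifier(
    "nbc", "discrete",
    train = function(x, y) {
      xf <- as_factors(x)
      list(fit = e1071::naiveBayes(xf, factor(y), laplace = laplace),
           levels = lapply(xf, levels))
    },
    predict = function(model, x) {
      xf <- as.data.frame(x)
      for (j in seq_along(xf))
        xf[[j]] <- factor(xf[[j]], levels = model$levels[[j]])
      as.character(stats::predict(model$fit, xf))
    })
}

#' Support-vector-machine classifier adapter
#'
#' Wraps [e1071::svm()] with its default (radial) kernel on the original
#' feature values.
#'
#' @param ... Passed through to [e1071::svm()].
#' @return A classifier adapter for [evaluate_cv()].
#' @export
classifier_svm <- function(...) {
  .new_classifier(
    "svm", "original",
    train = function(x, y) e1071::svm(as.matrix(x), factor(y), ...),
    predict = function(model, x)
      as.character(stats::predict(model, as.matrix(x))))
}

#' Majority-vote baseline adapter
#'
#' Ignores the features and always predicts the most frequent training
#' label; a chance-level baseline for sanity checks.
#'
#' @return A classifier adapter for [evaluate_cv()].
#' @export
classifier_majority <- function() {
  .new_classifier(
    "majority", "original",
    train = function(x, y) names(which.max(table(y))),
    predict = function(model, x) rep(model, nrow(as.data.frame(x))))
}

# resolve "knn"/"nbc"/"svm"/"majority" shorthand
.resolve_classifier <- function(cl, knn_k = 5) {
  if (inherits(cl, "wbfs_classifier")) return(cl)
  switch(as.character(cl),
         knn = classifier_knn(knn_k),
         nbc = classifier_nbc(),
         svm = classifier_svm(),
         majority = classifier_majority(),
         stop("unknown classifier \"", cl,
              "\" (expected knn, nbc, svm or majority)", call. = FALSE))
}
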