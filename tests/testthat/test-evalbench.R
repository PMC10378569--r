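test_that("the difficulty ratio reproduces the printed benchmark rows", {
  expect_identical(dataset_ratio(5000, 5, 3), 333L)
  expect_identical(dataset_ratio(6598, 5, 2), 660L)  # 659.8 rounds up
  expect_identical(dataset_ratio(2600, 5, 2), 260L)
  expect_identical(dataset_ratio(100, 1, 1), 100L)
  expect_identical(dataset_ratio(5, 2, 1), 3L)       # half away from zero
  expect_error(dataset_ratio(0, 5, 2), "positive")
  expect_error(dataset_ratio(100, -1, 2), "positive")
})

test_that("stratified folds keep class proportions within one sample", {
  set.seed(4)
  labels <- sample(c("A", "B", "C"), 97, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
  folds <- wbfs:::.stratified_folds(labels, 10)
  expect_equal(sort(unlist(folds)), 1:97)
  for (cl in unique(labels)) {
    per_fold <- vapply(folds, function(f) sum(labels[f] == cl), numeric(1))
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("a separable feature yields perfect held-out accuracy", {
  ft <- separable_table(n = 60, noise = 3, seed = 2)
  for (cl in c("knn", "nbc")) {
    rep <- evaluate_cv(ft, "wbfs", cl, K = 1, folds = 5, bins = 5, seed = 9)
    expect_equal(rep$mean, 1.0)
    expect_equal(rep$method, "wbfs")
    expect_length(rep$accuracies, 5)
    expect_equal(rep$sd, stats::sd(rep$accuracies))
  }
})

test_that("pure noise with a majority-vote baseline sits at chance", {
  set.seed(8)
  n <- 200
  vals <- matrix(stats::runif(n * 5), n, 5,
                 dimnames = list(NULL, paste0("ns", 1:5)))
  ft <- feature_table(vals, rep(c("A", "B"), n / 2))
  rep <- evaluate_cv(ft, "mim", classifier_majority(), K = 3, folds = 10,
                     seed = 3)
  # balanced binary classes: majority vote hits one class only
  expect_lt(abs(rep$mean - 0.5), 3 * sqrt(0.25 / n))
})

test_that("evaluation is reproducible under a fixed seed", {
  set.seed(6)  # weak signal so fold accuracies actually vary
  vals <- matrix(stats::runif(300), 60, 5,
                 dimnames = list(NULL, paste0("f", 1:5)))
  cl <- rep(c("A", "B"), 30)
  vals[, 1] <- vals[, 1] + ifelse(cl == "A", 0, 0.4)
  ft <- feature_table(vals, cl)
  r1 <- evaluate_cv(ft, "mrmr", "knn", K = 2, folds = 5, seed = 11)
  r2 <- evaluate_cv(ft, "mrmr", "knn", K = 2, folds = 5, seed = 11)
  expect_identical(r1, r2)
  r3 <- evaluate_cv(ft, "mrmr", "knn", K = 2, folds = 5, seed = 12)
  expect_false(identical(r1$accuracies, r3$accuracies))
})

test_that("discretization policy can replicate up-front binning", {
  ft <- separable_table(n = 40, noise = 2, seed = 10)
  full <- evaluate_cv(ft, "mim", "nbc", K = 1, folds = 4, seed = 5,
                      fit_bins_on = "full")
  train <- evaluate_cv(ft, "mim", "nbc", K = 1, folds = 4, seed = 5,
                       fit_bins_on = "train")
  expect_equal(full$fit_bins_on, "full")
  expect_equal(train$fit_bins_on, "train")
  expect_length(full$accuracies, 4)
})

test_that("the accuracy curve has one point per prefix and matches K=1", {
  ft <- separable_table(n = 50, noise = 3, seed = 13)
  curve <- accuracy_curve(ft, "wbfs", list("nbc"), k_max = 4, folds = 5,
                          seed = 17)
  expect_length(curve$mean_accuracy, 4)
  expect_equal(as.data.frame(curve)$k, 1:4)
  single <- evaluate_cv(ft, "wbfs", "nbc", K = 1, folds = 5, seed = 17)
  expect_equal(curve$mean_accuracy[1], single$mean)
  # noise-free separable signal: the curve never dips below chance
  expect_true(all(curve$mean_accuracy >= 0.5))
})

test_that("win/tie/loss decisions follow the paired t-test", {
  mk <- function(acc, method = "wbfs") {
    structure(list(method = method, classifier = "knn", K = 2,
                   folds = length(acc), bins = 5, seed = 1,
                   fit_bins_on = "train", select_on = "train",
                   accuracies = acc, mean = mean(acc),
                   sd = stats::sd(acc)),
              class = "cv_report")
  }
  a <- mk(rep(0.8, 10))
  expect_equal(compare_wtl(a, mk(rep(0.8, 10)))$decision, "Tie")
  expect_true(is.na(compare_wtl(a, mk(rep(0.8, 10)))$p_value))
  # +0.10 advantage with tiny per-fold jitter: decisive at alpha 0.1
  set.seed(19)
  base <- rep(0.7, 10)
  ref <- mk(base + 0.10 + stats::rnorm(10, 0, 0.001))
  cmp <- compare_wtl(ref, mk(base, "mim"))
  expect_equal(cmp$decision, "Win")
  expect_lt(cmp$p_value, 1e-6)
  # mirrored arguments flip the verdict at equal p
  rev <- compare_wtl(mk(base, "mim"), ref)
  expect_equal(rev$decision, "Loss")
  expect_equal(rev$p_value, cmp$p_value)
  # alpha 0 can never be significant
  expect_equal(compare_wtl(ref, mk(base, "mim"), alpha = 0)$decision, "Tie")
  expect_error(compare_wtl(a, mk(rep(0.8, 5))), "folds")
})
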