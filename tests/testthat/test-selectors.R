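test_that("the worked fixture selects (f3, f1, f2) with the known scores", {
  d <- t8_table()
  tr <- select_features(d, "wbfs", K = 3)
  expect_equal(tr$selected, c("f3", "f1", "f2"))
  expect_equal(tr$step_scores, c(0.1887218755, 0.4081722, 2.1375763),
               tolerance = 1e-6)
  # audit record of the winner's per-pair contributions at the last step
  terms <- tr$omega_terms[[3]]
  expect_equal(terms$fj, c("f3", "f1"))
  expect_equal(terms$omega, c(1.1225562, 2.0), tolerance = 1e-6)
  expect_equal(terms$cmi, c(0.1225562, 1.0), tolerance = 1e-6)
  # direct candidate scoring agrees with the frozen values
  expect_equal(score_wbfs_candidate(d, "f3", "f1"), 0.4081722,
               tolerance = 1e-6)
  expect_equal(score_wbfs_candidate(d, "f3", "f2"), 0.1375763,
               tolerance = 1e-6)
  expect_equal(score_wbfs_candidate(d, c("f3", "f1"), "f2"), 2.1375763,
               tolerance = 1e-6)
})

test_that("relevance-only ranking breaks ties by column order", {
  tr <- select_features(t8_table(), "mim", K = 3)
  expect_equal(tr$selected, c("f3", "f1", "f2"))
  expect_equal(tr$step_scores, c(0.1887218755, 0, 0), tolerance = 1e-9)
})

test_that("a perfect predictor saturates the criterion", {
  set.seed(5)
  cl <- sample(0:1, 40, replace = TRUE)
  codes <- cbind(a = sample(0:1, 40, replace = TRUE),
                 perfect = cl,
                 b = sample(0:1, 40, replace = TRUE))
  d <- discrete_table(codes, cl)
  tr <- select_features(d, "wbfs", K = 3)
  expect_equal(tr$selected[1], "perfect")
  expect_equal(tr$step_scores[1], entropy(cl))
  # every conditional score given the perfect feature vanishes,
  # so later picks fall back to column order
  expect_equal(max(abs(tr$candidate_scores[[2]])), 0, tolerance = 1e-12)
  expect_equal(tr$selected[2:3], c("a", "b"))
})

test_that("every criterion opens with the relevance maximum", {
  crits <- c("wbfs", "mim", "mifs", "mrmr", "cife", "condred", "disr")
  for (seed in 1:5) {
    d <- random_discrete(m = 6, n = 40, arity = 3, seed = seed)
    rel <- vapply(seq_len(6), function(j)
      mutual_information(d$codes[, j], d$class_codes), numeric(1))
    best <- d$feature_names[which.max(rel)]
    for (cr in crits)
      expect_equal(select_features(d, cr, K = 2)$selected[1], best)
  }
})

test_that("per-step candidate scores match brute-force recomputation", {
  crits <- c("wbfs", "mim", "mifs", "mrmr", "cife", "condred", "disr")
  for (seed in 1:6) {
    set.seed(seed + 100)
    m <- sample(3:6, 1)
    d <- random_discrete(m = m, n = sample(20:50, 1),
                         arity = sample(2:3, 1), seed = seed)
    for (cr in crits) {
      tr <- rank_full(d, cr)
      sel <- integer(0)
      for (step in seq_len(m)) {
        remaining <- setdiff(seq_len(m), sel)
        want <- vapply(remaining, function(k)
          oracle_candidate_score(cr, d$codes, d$class_codes, sel, k),
          numeric(1))
        got <- tr$candidate_scores[[step]]
        expect_equal(unname(got), want, tolerance = 1e-10)
        wmax <- max(want)
        wi <- which(want >= wmax - 1e-9 * max(1, abs(wmax)))[1]
        expect_equal(tr$selected[step], d$feature_names[remaining[wi]])
        sel <- c(sel, tr$selected_idx[step])
      }
    }
  }
})

test_that("the selected order does not depend on the log base", {
  for (cr in c("wbfs", "mrmr", "cife", "disr")) {
    for (seed in 1:4) {
      d <- random_discrete(m = 7, n = 45, arity = 3, seed = seed * 13)
      o2 <- rank_full(d, criterion_spec(cr, log_base = 2))$selected
      oe <- rank_full(d, criterion_spec(cr, log_base = exp(1)))$selected
      expect_equal(oe, o2)
    }
  }
})

test_that("permuting input columns permutes a tie-free ranking identically", {
  set.seed(21)
  cl <- sample(0:1, 60, replace = TRUE)
  codes <- cbind(u = ifelse(stats::runif(60) < 0.8, cl, 1L - cl),
                 v = ifelse(stats::runif(60) < 0.65, cl, 1L - cl),
                 w = sample(0:1, 60, replace = TRUE))
  d1 <- discrete_table(codes, cl)
  d2 <- discrete_table(codes[, c("w", "u", "v")], cl)
  expect_equal(rank_full(d1, "wbfs")$selected, rank_full(d2, "wbfs")$selected)
})

test_that("an XOR partner outruns noise under the weighted criterion", {
  set.seed(77)
  n <- 2000
  cl <- sample(0:1, n, replace = TRUE)
  a <- sample(0:1, n, replace = TRUE)
  b <- bitwXor(cl, a)
  codes <- cbind(a = a, b = b,
                 ns1 = sample(0:1, n, replace = TRUE),
                 ns2 = sample(0:1, n, replace = TRUE))
  d <- discrete_table(codes, cl)
  # with one parent selected, the partner's score dwarfs any noise feature
  sb <- score_wbfs_candidate(d, "a", "b")
  s1 <- score_wbfs_candidate(d, "a", "ns1")
  s2 <- score_wbfs_candidate(d, "a", "ns2")
  expect_gt(sb, 0.9)                # ~1 bit of revealed synergy
  expect_gt(sb, 10 * max(s1, s2))
  # the relevance-redundancy trade-off gives the partner no such boost:
  # its mRMR score stays at chance level (population value 0)
  mrmr_b <- mutual_information(b, cl) - mutual_information(b, a)
  expect_lt(mrmr_b, 0.01)
})

test_that("a redundant copy scores below an equally-relevant independent feature", {
  set.seed(31)
  n <- 3000
  cl <- sample(0:1, n, replace = TRUE)
  flip <- function(v, p) ifelse(stats::runif(n) < p, 1L - v, v)
  orig <- flip(cl, 0.1)
  dup <- flip(orig, 0.05)        # noisy duplicate of the selected feature
  indep <- flip(cl, 0.126)       # matched relevance, independent noise path
  d <- discrete_table(cbind(orig = orig, dup = dup, indep = indep), cl)
  expect_lt(score_wbfs_candidate(d, "orig", "dup"),
            score_wbfs_candidate(d, "orig", "indep"))
})

test_that("contract violations are rejected", {
  d <- t8_table()
  expect_error(select_features(d, "wbfs", K = 4), "exceeds")
  expect_error(select_features(d, "wbfs", K = 0), "positive")
  expect_error(score_wbfs_candidate(d, "f3", "f3"), "already selected")
  expect_error(score_wbfs_candidate(d, "f9", "f1"), "unknown feature")
  expect_error(score_wbfs_candidate(d, character(), "f1"), "nonempty")
  expect_error(criterion_spec("jmi"))
  flat <- discrete_table(t8_codes(), rep(0L, 8))
  expect_error(select_features(flat, "wbfs", 2), "constant")
})
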