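#' Specify a forward-selection criterion
#'
#' All supported criteria are greedy forward rankers: at every step the
#' candidate maximising the criterion's score `J` given the already-selected
#' set `S` is appended. With `S` empty each score reduces to the plain
#' relevance `I(f;C)`, so every criterion picks the same first feature.
#'
#' Scores for a candidate `fk` given selected set `S` and class `C`:
#' \describe{
#'   \item{wbfs}{`J = sum_{fj in S} omega(fj, fk, C) * I(fk;C|fj)` with the
#'     interaction-gain weight of [weight_omega()].}
#'   \item{mim}{`J = I(fk;C)` (relevance only).}
#'   \item{mifs}{`J = I(fk;C) - beta * sum_{fj in S} I(fk;fj)`.}
#'   \item{mrmr}{`J = I(fk;C) - (1/|S|) * sum_{fj in S} I(fk;fj)`.}
#'   \item{cife}{`J = I(fk;C) - sum I(fk;fj) + sum I(fk;fj|C)`.}
#'   \item{condred}{`J = I(fk;C) + sum_{fj in S} I(fk;fj|C)`.}
#'   \item{disr}{`J = sum_{fj in S} I((fk,fj);C) / H(fk,fj,C)`, the joint
#'     relevance of each pair normalised by the three-way joint entropy.}
#' }
#'
#' @param name One of `"wbfs"`, `"mim"`, `"mifs"`, `"mrmr"`, `"cife"`,
#'   `"condred"`, `"disr"`.
#' @param beta Redundancy coefficient, used by MIFS only (default 1).
#' @param log_base Logarithm base for the information estimates (default 2).
#'   The selected order is base-invariant; the base only rescales scores.
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(name = c("wbfs", "mim", "mifs", "mrmr",
                                    "cife", "condred", "disr"),
                           beta = 1, log_base = 2) {
  name <- match.arg(name)
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(log_base), length(log_base) == 1L, log_base > 1)
  structure(list(name = name, beta = beta, log_base = log_base),
            class = "criterion_spec")
}

#' @export
print.criterion_spec <- function(x, ...) {
  cat("criterion_spec:", x$name,
      if (x$name == "mifs") sprintf("(beta = %g)", x$beta),
      sprintf("[log base %g]\n", x$log_base))
  invisible(x)
}

# resolve feature names/indices against a discrete_table
.feature_index <- function(data, f) {
  if (is.numeric(f)) {
    idx <- as.integer(f)
    if (any(idx < 1L | idx > ncol(data$codes)))
      stop("feature index out of range", call. = FALSE)
    return(idx)
  }
  idx <- match(f, data$feature_names)
  if (anyNA(idx))
    stop("unknown feature name(s): ",
         paste(f[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Score one candidate under the WBFS criterion
#'
#' Direct (non-incremental) evaluation of the weighted conditional-relevance
#' sum `J(fk) = sum_{fj in S} omega(fj, fk, C) * I(fk;C|fj)` for a single
#' candidate, mainly for audit of a [select_features()] run.
#'
#' @param data A [discrete_table].
#' @param selected Nonempty vector of selected feature names (or indices).
#' @param fk Candidate feature name (or index), not among `selected`.
#' @param log_base Logarithm base (default 2).
#' @return The score `J` (a nonnegative number).
#' @export
score_wbfs_candidate <- function(data, selected, fk, log_base = 2) {
  stopifnot(inherits(data, "discrete_table"))
  if (length(selected) == 0L)
    stop("`selected` must be nonempty", call. = FALSE)
  sel <- .feature_index(data, selected)
  k <- .feature_index(data, fk)
  if (length(k) != 1L) stop("`fk` must name a single feature", call. = FALSE)
  if (k %in% sel) stop("candidate is already selected", call. = FALSE)
  cy <- data$class_codes
  xk <- data$codes[, k]
  total <- 0
  for (j in sel) {
    xj <- data$codes[, j]
    total <- total + weight_omega(xj, xk, cy, log_base) *
      conditional_mutual_information(xk, cy, xj, log_base)
  }
  total
}

#' Greedy forward feature selection
#'
#' Runs the greedy ranking defined by a [criterion_spec()]: the first feature
#' maximises `I(f;C)`; each subsequent step scores every remaining candidate
#' and appends the single argmax. Scores within a relative `1e-9` of the
#' step maximum count as tied and the lowest original column index wins, so
#' runs are deterministic and the order cannot flip with the logarithm
#' base on mathematically tied scores.
#'
#' All pairwise information terms are computed once per (selected, candidate)
#' pair: when a feature enters the selected set its contribution is added to
#' each remaining candidate's running score, which keeps the cost of ranking
#' `K` features linear in `K * m * n`.
#'
#' @param data A [discrete_table] with at least 2 class codes.
#' @param criterion A [criterion_spec()] (or a criterion name, which is
#'   promoted with default parameters).
#' @param K Number of features to select, `1 <= K <=` feature count.
#' @return An object of class `selection_trace`: `selected` (ordered names),
#'   `step_scores` (winning `J` per step), `candidate_scores` (per step, the
#'   named score vector over all remaining candidates), and for WBFS
#'   `omega_terms` (per step, the winner's per-`fj` weight and conditional
#'   mutual information contributions).
#' @examples
#' codes <- cbind(f1 = c(0,0,1,1,0,0,1,1), f2 = c(0,1,0,1,0,1,0,1),
#'                f3 = c(0,1,1,0,0,1,0,1))
#' cls <- c(0,1,1,0,0,1,1,0)           # = f1 XOR f2
#' d <- discrete_table(codes, cls)
#' select_features(d, "wbfs", K = 3)$selected
#' @export
select_features <- function(data, criterion, K) {
  stopifnot(inherits(data, "discrete_table"))
  if (is.character(criterion)) criterion <- criterion_spec(criterion)
  stopifnot(inherits(criterion, "criterion_spec"))
  m <- ncol(data$codes)
  n <- nrow(data$codes)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("`K` must be a single positive integer", call. = FALSE)
  if (K > m)
    stop(sprintf("K = %d exceeds the number of features (%d)", K, m),
         call. = FALSE)
  if (data$n_classes < 2L)
    stop("class is constant; selection needs >= 2 class codes", call. = FALSE)
  K <- as.integer(K)
  base <- criterion$log_base

  cols <- lapply(seq_len(m), function(j) .compact(data$codes[, j]))
  cy <- .compact(data$class_codes)
  mi2 <- function(a, b) max(0, .H(a, base) + .H(b, base) - .H(.pair(a, b), base))
  cmi3 <- function(a, b, z)
    max(0, .H(.pair(a, z), base) + .H(.pair(b, z), base) -
           .H(z, base) - .H(.pair(.pair(a, b), z), base))

  hC <- .H(cy, base)
  hF <- vapply(cols, .H, numeric(1), base = base)
  rel <- vapply(cols, mi2, numeric(1), b = cy)
  names(rel) <- data$feature_names

  selected <- integer(0)
  remaining <- seq_len(m)
  step_scores <- numeric(K)
  candidate_scores <- vector("list", K)
  # per-step contribution records (wbfs audit)
  omega_hist <- list(); cmi_hist <- list()
  # running accumulators over features (indexed by original column)
  accJ <- numeric(m)      # wbfs weighted sum
  accRed <- numeric(m)    # sum of I(fk;fj)
  accCond <- numeric(m)   # sum of I(fk;fj|C)
  accDisr <- numeric(m)   # sum of normalised joint relevances

  score_remaining <- function() {
    switch(criterion$name,
      wbfs = accJ[remaining],
      mim = rel[remaining],
      mifs = rel[remaining] - criterion$beta * accRed[remaining],
      mrmr = rel[remaining] - accRed[remaining] / length(selected),
      cife = rel[remaining] - accRed[remaining] + accCond[remaining],
      condred = rel[remaining] + accCond[remaining],
      disr = accDisr[remaining])
  }

  for (step in seq_len(K)) {
    if (step == 1L) {
      J <- rel[remaining]
    } else {
      J <- score_remaining()
    }
    names(J) <- data$feature_names[remaining]
    candidate_scores[[step]] <- J
    # scores within a relative 1e-9 of the maximum are ties; the lowest
    # original column index wins, so the order is deterministic and does
    # not flip with the logarithm base
    Jmax <- max(J)
    wi <- which(J >= Jmax - 1e-9 * max(1, abs(Jmax)))[1]
    win <- remaining[wi]
    step_scores[step] <- J[[wi]]
    selected <- c(selected, win)
    remaining <- setdiff(remaining, win)
    if (step == K || length(remaining) == 0L) break
    # fold the new member's pairwise terms into every remaining candidate
    xj <- cols[[win]]
    om <- cm <- stats::setNames(numeric(length(remaining)),
                                data$feature_names[remaining])
    for (i in seq_along(remaining)) {
      k <- remaining[i]
      xk <- cols[[k]]
      switch(criterion$name,
        wbfs = {
          denom <- hF[win] + hC
          w <- if (denom == 0) 1 else
            1 + 2 * (cmi3(xj, cy, xk) - rel[win]) / denom
          ck <- cmi3(xk, cy, xj)
          om[i] <- w; cm[i] <- ck
          accJ[k] <- accJ[k] + w * ck
        },
        mim = NULL,
        mifs = accRed[k] <- accRed[k] + mi2(xk, xj),
        mrmr = accRed[k] <- accRed[k] + mi2(xk, xj),
        cife = {
          accRed[k] <- accRed[k] + mi2(xk, xj)
          accCond[k] <- accCond[k] + cmi3(xk, xj, cy)
        },
        condred = accCond[k] <- accCond[k] + cmi3(xk, xj, cy),
        disr = {
          pair_k <- .pair(xk, xj)
          hJoint <- .H(.pair(pair_k, cy), base)
          accDisr[k] <- accDisr[k] +
            if (hJoint == 0) 0 else mi2(pair_k, cy) / hJoint
        })
    }
    if (criterion$name == "wbfs") {
      omega_hist[[step]] <- om
      cmi_hist[[step]] <- cm
    }
  }

  sel_names <- data$feature_names[selected]
  omega_terms <- NULL
  if (criterion$name == "wbfs" && K > 1L) {
    omega_terms <- vector("list", K)
    for (step in 2:K) {
      winner <- sel_names[step]
      omega_terms[[step]] <- data.frame(
        fj = sel_names[seq_len(step - 1L)],
        omega = vapply(seq_len(step - 1L),
                       function(s) omega_hist[[s]][[winner]], numeric(1)),
        cmi = vapply(seq_len(step - 1L),
                     function(s) cmi_hist[[s]][[winner]], numeric(1)))
    }
  }
  structure(
    list(selected = sel_names,
         selected_idx = selected,
         step_scores = step_scores,
         candidate_scores = candidate_scores,
         omega_terms = omega_terms,
         criterion = criterion,
         n_samples = n, n_features = m),
    class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace (%s): %d of %d features\n",
              x$criterion$name, length(x$selected), x$n_features))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$selected) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.selection_trace <- function(x, ...) {
  data.frame(rank = seq_along(x$selected),
             feature = x$selected,
             score = x$step_scores)
}

#' Rank all features
#'
#' [select_features()] with `K` equal to the feature count: a full ordering
#' of the features under the given criterion.
#'
#' @inheritParams select_features
#' @return A `selection_trace` of length `m`.
#' @export
rank_full <- function(data, criterion) {
  select_features(data, criterion, K = ncol(data$codes))
}

#' Write a ranking to TSV
#'
#' Columns `rank`, `feature`, `score`; one row per selected feature.
#'
#' @param trace A `selection_trace`.
#' @param path Output path.
#' @export
write_ranking <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
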