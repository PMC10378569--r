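#' Specify a planted-structure synthetic dataset
#'
#' Describes a tabular dataset with known ground truth, built from four
#' feature blocks around a uniformly drawn class:
#' \describe{
#'   \item{relevant}{noisy copies of the class code (symmetric flip to a
#'     random other code with probability `flip_probability`);}
#'   \item{redundant}{re-flipped duplicates of relevant features — relevant
#'     on their own, but nearly useless once their original is selected;}
#'   \item{xor pairs}{(binary class only) parent A uniform, parent B equal
#'     to class XOR A, each then flipped at `pair_flip_probability`: each
#'     parent is marginally independent of the class, while the pair
#'     determines it — the purely interacting structure that relevance-only
#'     criteria miss;}
#'   \item{noise}{independent uniform codes.}
#' }
#' With `continuous_jitter = TRUE` each code receives additive uniform
#' noise in `(-0.4, 0.4)` — less than half the unit code spacing — so
#' equal-width binning with as many bins as the arity recovers the codes.
#'
#' @param n_samples Number of samples.
#' @param n_classes Number of classes (default 2).
#' @param n_relevant Number of noisy class copies.
#' @param flip_probability Flip rate of relevant features, in `[0, 0.5]`.
#' @param n_redundant Number of noisy duplicates of relevant features
#'   (requires `n_relevant > 0`).
#' @param duplicate_noise Re-flip rate of the duplicates, in `[0, 0.5]`.
#' @param n_xor_pairs Number of XOR parent pairs (binary class only).
#' @param pair_flip_probability Flip rate of each XOR parent, in `[0, 0.5]`.
#' @param n_noise Number of independent uniform noise features.
#' @param noise_arity Number of codes a noise feature takes (default 2).
#' @param continuous_jitter Add sub-bin uniform jitter so the table is
#'   continuous-valued (default `TRUE`).
#' @param seed Integer seed (can be overridden in [generate_synthetic()]).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, n_classes = 2, n_relevant = 0,
                           flip_probability = 0.1, n_redundant = 0,
                           duplicate_noise = 0.1, n_xor_pairs = 0,
                           pair_flip_probability = 0.05, n_noise = 0,
                           noise_arity = 2, continuous_jitter = TRUE,
                           seed = 1) {
  stopifnot(n_samples >= 1, n_classes >= 2,
            n_relevant >= 0, n_redundant >= 0, n_xor_pairs >= 0,
            n_noise >= 0, noise_arity >= 2)
  if (n_relevant + n_redundant + 2 * n_xor_pairs + n_noise < 1)
    stop("spec describes zero features", call. = FALSE)
  for (p in c(flip_probability, duplicate_noise, pair_flip_probability))
    if (p < 0 || p > 0.5)
      stop("flip probabilities must lie in [0, 0.5]", call. = FALSE)
  if (n_xor_pairs > 0 && n_classes != 2)
    stop("XOR pairs require a binary class", call. = FALSE)
  if (n_redundant > 0 && n_relevant == 0)
    stop("redundant features require at least one relevant feature",
         call. = FALSE)
  structure(as.list(environment())[
    c("n_samples", "n_classes", "n_relevant", "flip_probability",
      "n_redundant", "duplicate_noise", "n_xor_pairs",
      "pair_flip_probability", "n_noise", "noise_arity",
      "continuous_jitter", "seed")],
    class = "synthetic_spec")
}

# symmetric flip: with probability p, replace the code by a uniformly
# drawn *different* code from 0..arity-1 (ordinary XOR flip when arity 2)
.flip <- function(codes, p, arity) {
  if (p == 0) return(codes)
  hit <- stats::runif(length(codes)) < p
  if (any(hit)) {
    shift <- sample.int(arity - 1L, sum(hit), replace = TRUE)
    codes[hit] <- (codes[hit] + shift) %% arity
  }
  codes
}

#' Generate a planted-structure dataset
#'
#' Draws the dataset described by a [synthetic_spec()]. The same seed always
#' produces an identical table.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to the one in `spec`.
#' @return List with `table` (a [feature_table]) and `truth` (a data frame
#'   with one row per feature: `feature`, `role` in
#'   `c("relevant", "redundant", "xor_parent", "noise")`, and `pair_id`
#'   linking XOR parents).
#' @examples
#' sim <- generate_synthetic(
#'   synthetic_spec(200, n_relevant = 1, flip_probability = 0, seed = 7))
#' table(sim$truth$role)
#' @export
generate_synthetic <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_samples
  cls <- sample.int(spec$n_classes, n, replace = TRUE) - 1L

  cols <- list(); roles <- character(); pair_ids <- integer()
  add <- function(name, codes, role, pair = NA_integer_) {
    cols[[name]] <<- codes
    roles <<- c(roles, role)
    pair_ids <<- c(pair_ids, pair)
  }
  relevant_names <- character()
  for (i in seq_len(spec$n_relevant)) {
    nm <- paste0("rel", i)
    add(nm, .flip(cls, spec$flip_probability, spec$n_classes), "relevant")
    relevant_names <- c(relevant_names, nm)
  }
  for (i in seq_len(spec$n_redundant)) {
    src <- relevant_names[((i - 1L) %% spec$n_relevant) + 1L]
    add(paste0("red", i),
        .flip(cols[[src]], spec$duplicate_noise, spec$n_classes),
        "redundant")
  }
  for (i in seq_len(spec$n_xor_pairs)) {
    a <- sample.int(2L, n, replace = TRUE) - 1L
    b <- bitwXor(cls, a)
    add(paste0("xorA", i), .flip(a, spec$pair_flip_probability, 2L),
        "xor_parent", i)
    add(paste0("xorB", i), .flip(b, spec$pair_flip_probability, 2L),
        "xor_parent", i)
  }
  for (i in seq_len(spec$n_noise))
    add(paste0("noise", i),
        sample.int(spec$noise_arity, n, replace = TRUE) - 1L, "noise")

  values <- do.call(cbind, cols)
  storage.mode(values) <- "double"
  if (spec$continuous_jitter)
    values <- values + matrix(stats::runif(length(values), -0.4, 0.4),
                              nrow = n)
  list(table = feature_table(values, paste0("c", cls)),
       truth = data.frame(feature = names(cols), role = roles,
                          pair_id = pair_ids))
}

#' Fraction of planted features recovered in a top-k prefix
#'
#' The targets are the planted relevant features and XOR parents (redundant
#' duplicates are not targets — a good selector should skip them). Returns
#' the fraction of targets present among the first `top_k` entries of a
#' selection trace.
#'
#' @param trace A `selection_trace` from [select_features()].
#' @param truth Ground-truth data frame from [generate_synthetic()].
#' @param top_k Prefix length, at most the trace length.
#' @return Fraction in `[0, 1]`.
#' @export
recovery_score <- function(trace, truth, top_k) {
  stopifnot(inherits(trace, "selection_trace"))
  if (top_k > length(trace$selected))
    stop("`top_k` exceeds the trace length", call. = FALSE)
  targets <- truth$feature[truth$role %in% c("relevant", "xor_parent")]
  if (length(targets) == 0L)
    stop("ground truth contains no planted target features", call. = FALSE)
  mean(targets %in% trace$selected[seq_len(top_k)])
}
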