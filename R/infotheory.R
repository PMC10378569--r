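# Plug-in (empirical frequency) information estimators on integer-coded
# vectors. Joint quantities are computed by pairing codes into a single
# compact index and reusing the entropy identity, e.g.
# I(X;Y) = H(X) + H(Y) - H(X,Y); for plug-in estimates this is exactly the
# cell-by-cell contingency sum with the 0*log(0) := 0 convention.

# compact 1-based codes, first-appearance order
.compact <- function(x) match(x, unique(x))

# pair two compact code vectors into one compact joint code
.pair <- function(ix, iy) .compact((ix - 1L) * max(iy) + iy)

.check_codes <- function(x, arg) {
  if (length(x) == 0L) stop("`", arg, "` is empty", call. = FALSE)
  if (anyNA(x)) stop("`", arg, "` contains NA", call. = FALSE)
}

.check_lengths <- function(...) {
  lens <- lengths(list(...))
  if (length(unique(lens)) != 1L)
    stop("coded vectors differ in length (",
         paste(lens, collapse = ", "), ")", call. = FALSE)
}

# entropy of compact codes, in units of `base`
.H <- function(ix, base) {
  n <- length(ix)
  cnt <- tabulate(ix)
  cnt <- cnt[cnt > 0L]
  p <- cnt / n
  -sum(p * log(p)) / log(base)
}

#' Plug-in entropy
#'
#' Empirical Shannon entropy `H = -sum p log p` over the observed symbols of
#' an integer-coded (or any discrete) vector, with `0 * log 0 := 0`.
#'
#' @param x Discrete vector (integer codes, factor, character, ...).
#' @param base Logarithm base (default 2: bits).
#' @return Entropy in `base` units, in `[0, log_base(arity)]`.
#' @examples
#' entropy(c(0, 1, 0, 1))        # 1 bit
#' entropy(c(0, 0, 0, 1))        # 0.811 bits
#' @export
entropy <- function(x, base = 2) {
  .check_codes(x, "x")
  .H(.compact(x), base)
}

#' Plug-in mutual information
#'
#' `I(X;Y) = sum_xy p(x,y) log( p(x,y) / (p(x) p(y)) )` from the empirical
#' joint frequencies. Symmetric, nonnegative, bounded by `min(H(X), H(Y))`.
#'
#' @param x,y Discrete vectors of equal length.
#' @param base Logarithm base (default 2).
#' @return Mutual information in `base` units.
#' @export
mutual_information <- function(x, y, base = 2) {
  .check_codes(x, "x"); .check_codes(y, "y")
  .check_lengths(x, y)
  ix <- .compact(x); iy <- .compact(y)
  max(0, .H(ix, base) + .H(iy, base) - .H(.pair(ix, iy), base))
}

#' Plug-in conditional mutual information
#'
#' `I(X;Y|Z) = sum_z p(z) I(X;Y | Z = z)`: the mutual information of `x` and
#' `y` within each stratum of `z`, averaged under the empirical distribution
#' of `z`. Equals `mutual_information(x, y)` when `z` is constant; strata
#' with zero mass contribute nothing.
#'
#' @param x,y,z Discrete vectors of equal length; `z` is the conditioning
#'   variable.
#' @param base Logarithm base (default 2).
#' @return Conditional mutual information in `base` units (nonnegative).
#' @export
conditional_mutual_information <- function(x, y, z, base = 2) {
  .check_codes(x, "x"); .check_codes(y, "y"); .check_codes(z, "z")
  .check_lengths(x, y, z)
  ix <- .compact(x); iy <- .compact(y); iz <- .compact(z)
  # plug-in identity: I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)
  max(0, .H(.pair(ix, iz), base) + .H(.pair(iy, iz), base) -
         .H(iz, base) - .H(.pair(.pair(ix, iy), iz), base))
}

#' Three-way interaction information
#'
#' `I(X;Y;Z) = I(X,Y;Z) - I(X;Z) - I(Y;Z)`, where `(X,Y)` is the joint
#' variable formed by pairing codes. Positive values indicate synergy (the
#' pair carries information about `z` that neither member carries alone,
#' e.g. a noise-free XOR triple gives +1 bit); negative values indicate
#' redundancy.
#'
#' @param x,y,z Discrete vectors of equal length.
#' @param base Logarithm base (default 2).
#' @return Signed interaction information in `base` units.
#' @export
interaction_information <- function(x, y, z, base = 2) {
  .check_codes(x, "x"); .check_codes(y, "y"); .check_codes(z, "z")
  .check_lengths(x, y, z)
  ix <- .compact(x); iy <- .compact(y); iz <- .compact(z)
  mi <- function(a, b) max(0, .H(a, base) + .H(b, base) - .H(.pair(a, b), base))
  mi(.pair(ix, iy), iz) - mi(ix, iz) - mi(iy, iz)
}

#' Interaction-gain weight of a selected feature
#'
#' The per-pair multiplier used by the WBFS criterion:
#' `omega = 1 + 2 * (I(fj;C|fk) - I(fj;C)) / (H(fj) + H(C))`.
#' It exceeds 1 when the candidate `fk` increases what the already-selected
#' feature `fj` says about the class (positive interaction), and falls below
#' 1 when `fk` makes `fj` redundant. The normalisation bounds it in
#' `[0, 2]`; a noise-free XOR pair attains the upper bound exactly. When
#' both `fj` and `c` are constant (`H(fj) + H(C) = 0`) all information terms
#' vanish and the neutral weight 1 is returned.
#'
#' @param fj Codes of the already-selected feature.
#' @param fk Codes of the candidate feature.
#' @param c Class codes.
#' @param base Logarithm base; the weight is a ratio of information
#'   quantities and therefore base-invariant.
#' @return The weight, a number in `[0, 2]`.
#' @export
weight_omega <- function(fj, fk, c, base = 2) {
  .check_codes(fj, "fj"); .check_codes(fk, "fk"); .check_codes(c, "c")
  .check_lengths(fj, fk, c)
  denom <- entropy(fj, base) + entropy(c, base)
  if (denom == 0) return(1)
  num <- conditional_mutual_information(fj, c, fk, base) -
    mutual_information(fj, c, base)
  1 + 2 * num / denom
}
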