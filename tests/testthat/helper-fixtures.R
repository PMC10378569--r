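# Eight-row worked fixture: the class equals f1 XOR f2 exactly, while f3
# agrees with the class in 6 of 8 rows. f1 and f2 carry zero marginal
# information about the class but determine it jointly.
t8_codes <- function() {
  cbind(f1 = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
        f2 = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
        f3 = c(0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L))
}

t8_class <- function() c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L)

t8_table <- function() discrete_table(t8_codes(), t8_class())

# random integer-coded table with a non-constant class
random_discrete <- function(m, n, arity = 3, n_classes = 2, seed = 1) {
  set.seed(seed)
  codes <- matrix(sample.int(arity, m * n, replace = TRUE) - 1L, n, m,
                  dimnames = list(NULL, paste0("f", seq_len(m))))
  cl <- sample.int(n_classes, n, replace = TRUE) - 1L
  cl[1:2] <- 0:1  # guarantee >= 2 classes
  discrete_table(codes, cl)
}

# feature table with one perfectly separating feature plus noise
separable_table <- function(n = 60, noise = 3, seed = 1) {
  set.seed(seed)
  cl <- rep(c("A", "B"), length.out = n)
  vals <- cbind(sig = ifelse(cl == "A", 0, 10) + stats::runif(n),
                matrix(stats::runif(n * noise, 0, 10), n,
                       dimnames = list(NULL, paste0("ns", seq_len(noise)))))
  feature_table(vals, cl)
}
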