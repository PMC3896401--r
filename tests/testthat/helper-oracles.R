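# Independent brute-force oracles used to pin expected values.

# Mean pairwise difference within a deme by explicit enumeration of all
# unordered individual pairs.
enum_within <- function(nA, na) {
  alleles <- c(rep("A", nA), rep("a", na))
  n <- length(alleles)
  stopifnot(n >= 2)
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Mean pairwise difference between two demes over all cross pairs.
enum_between <- function(nA_x, na_x, nA_y, na_y) {
  x <- c(rep("A", nA_x), rep("a", na_x))
  y <- c(rep("A", nA_y), rep("a", na_y))
  mean(outer(x, y, "!="))
}

enum_corrected <- function(nA_x, na_x, nA_y, na_y) {
  enum_between(nA_x, na_x, nA_y, na_y) -
    (enum_within(nA_x, na_x) + enum_within(nA_y, na_y)) / 2
}

# Direct O(N^2) discrete Fourier transform mean spectral frequency.
dft_fbar <- function(p) {
  N <- length(p)
  stopifnot(N %% 2 == 1)
  ks <- seq_len((N - 1) / 2)
  A <- vapply(ks, function(k) {
    Mod(sum(p * exp(-2i * pi * k * (seq_len(N) - 1) / N)))
  }, numeric(1))
  if (sum(A) < 1e-9) return(0)
  sum((ks / N) * A) / sum(A)
}

# Brute-force run-length scanner over the three deme classes.
scan_segments <- function(freq, eps = 0) {
  lab <- ifelse(freq >= 1 - eps, "A", ifelse(freq <= eps, "a", "mixed"))
  segs <- list()
  start <- 1
  for (i in seq_along(lab)) {
    if (i == length(lab) || lab[i + 1] != lab[i]) {
      segs[[length(segs) + 1]] <- list(label = lab[start], start = start,
                                       width = i - start + 1)
      start <- i + 1
    }
  }
  segs
}

# A small random column of deme counts at carrying capacity K, biased toward
# fixed demes so segmentation sees realistic mixtures of domains and clines.
random_column_counts <- function(N, K) {
  p <- sample(c(0, 1, runif(3)), N, replace = TRUE)
  nA <- rbinom(N, K, p)
  # force some exact fixations
  fix <- runif(N) < 0.4
  nA[fix] <- ifelse(p[fix] > 0.5, K, 0L)
  list(nA = as.integer(nA), na = as.integer(K - nA))
}

small_test_params <- function(...) {
  sim_params(n_rows = 11, n_cols = 30, K = 30, n_init_cols = 5,
             max_generations = 300, ...)
}
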