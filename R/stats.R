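#' Segment a column into homogeneous domains and clines
#'
#' Classifies every deme of a frozen-record column as homogeneous for allele A
#' (frequency 1), homogeneous for allele a (frequency 0), or genetically mixed.
#' A homogeneous domain is a maximal run of contiguous demes fixed for the
#' same allele; adjacent runs fixed for opposite alleles are distinct domains.
#' An allele-frequency cline is a maximal run of contiguous mixed demes.
#'
#' @param freq Numeric vector of allele-A frequencies in `[0, 1]`.
#' @param eps Half-width of the fixation band: a deme counts as homogeneous
#'   when its frequency is within `eps` of 0 or 1. The default 0 demands exact
#'   fixation, which is well defined because frequencies are multiples of
#'   `1/K`.
#' @return A `segmentation` object: list with data.frames `domains`
#'   (`allele`, `start_row`, `width`) and `clines` (`start_row`, `width`),
#'   counts `n_domains`, `n_clines`, and `mean_domain_width`,
#'   `mean_cline_width` (`NA` when the corresponding count is 0). Segments
#'   tile the column: the widths sum to `length(freq)`.
#' @examples
#' segment_column(c(1, 1, 1, 0.5, 0, 0))
#' @export
segment_column <- function(freq, eps = 0) {
  stopifnot(is.numeric(freq), length(freq) >= 1, eps >= 0, eps < 0.5)
  if (any(!is.finite(freq)) || any(freq < 0) || any(freq > 1))
    stop("frequencies must be finite and lie in [0, 1]", call. = FALSE)
  lab <- ifelse(freq >= 1 - eps, "A", ifelse(freq <= eps, "a", "mixed"))
  runs <- rle(lab)
  start <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  is_dom <- runs$values != "mixed"
  domains <- data.frame(allele = runs$values[is_dom],
                        start_row = start[is_dom],
                        width = runs$lengths[is_dom])
  clines <- data.frame(start_row = start[!is_dom],
                       width = runs$lengths[!is_dom])
  structure(list(
    domains = domains, clines = clines,
    n_domains = nrow(domains), n_clines = nrow(clines),
    mean_domain_width = if (nrow(domains)) mean(domains$width) else NA_real_,
    mean_cline_width = if (nrow(clines)) mean(clines$width) else NA_real_
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Column segmentation: %d domain(s), %d cline(s)\n",
              x$n_domains, x$n_clines))
  cat(sprintf("  mean widths: domains %s, clines %s demes\n",
              format(x$mean_domain_width), format(x$mean_cline_width)))
  invisible(x)
}

#' Mean frequency of the allele-frequency power spectrum
#'
#' Treats a column's allele-A frequencies as a spatial wave and summarises how
#' fine-grained its fluctuation is: with discrete Fourier transform
#' coefficients `P_k` of the frequency vector, amplitudes `A_k = |P_k|` for
#' `k = 1, ..., (N-1)/2` (the constant term is excluded; `N` odd so the
#' highest resolvable index is `(N-1)/2`), and spatial frequencies
#' `f_k = k / N` cycles per deme, it returns the amplitude-weighted mean
#' `sum(f_k * A_k) / sum(A_k)`. Higher values mean finer-scale fluctuation;
#' a constant column has an empty spectrum and returns 0 by convention.
#'
#' @param freq Numeric vector of length-`N` allele-A frequencies, `N` odd.
#' @return The mean spectral frequency, in cycles per deme, within
#'   `[1/N, (N-1)/(2N)]` for non-constant input and 0 for constant input.
#' @examples
#' i <- 0:74
#' mean_spectral_freq(0.5 + 0.4 * cos(2 * pi * 5 * i / 75))  # 5/75
#' @export
mean_spectral_freq <- function(freq) {
  N <- length(freq)
  stopifnot(is.numeric(freq), N >= 1)
  if (N %% 2 == 0)
    stop("column length must be odd for the mean spectral frequency", call. = FALSE)
  if (N == 1) return(0)
  P <- stats::fft(freq)
  k <- seq_len((N - 1L) %/% 2L)
  A <- Mod(P[k + 1L])
  total <- sum(A)
  if (total <= N * .Machine$double.eps * max(1, sum(abs(freq)))) return(0)
  sum((k / N) * A) / total
}

#' Average pairwise difference within one deme
#'
#' Mean number of allelic differences over all unordered pairs of individuals
#' in a deme, for one diallelic locus: `2 * nA * na / (n * (n - 1))` with
#' `n = nA + na`. This is the within-population nucleotide-diversity estimator
#' with the small-sample `n / (n - 1)` correction.
#'
#' @param nA,na Non-negative integer allele counts (vectorised).
#' @return Mean pairwise difference in `[0, 1]`; errors if any `nA + na < 2`.
#' @export
pairwise_within <- function(nA, na) {
  check_counts(nA, na)
  n <- nA + na
  if (any(n < 2)) stop("pairwise_within needs at least 2 individuals", call. = FALSE)
  2 * nA * na / (n * (n - 1))
}

#' Average pairwise difference between two demes
#'
#' Mean number of allelic differences over all cross-deme pairs of
#' individuals: `pX * (1 - pY) + pY * (1 - pX)` with `pX`, `pY` the allele-A
#' frequencies of the two demes.
#'
#' @param nA_x,na_x Allele counts of deme X (vectorised).
#' @param nA_y,na_y Allele counts of deme Y.
#' @return Mean cross-population pairwise difference in `[0, 1]`.
#' @export
pairwise_between <- function(nA_x, na_x, nA_y, na_y) {
  check_counts(nA_x, na_x)
  check_counts(nA_y, na_y)
  nx <- nA_x + na_x
  ny <- nA_y + na_y
  if (any(nx < 1) || any(ny < 1)) stop("both demes must be non-empty", call. = FALSE)
  px <- nA_x / nx
  py <- nA_y / ny
  px * (1 - py) + py * (1 - px)
}

#' Corrected average pairwise difference between two demes
#'
#' The between-population difference net of within-population diversity:
#' `PXY - (PX + PY) / 2` (the Nei/Takahata correction). Positive values
#' indicate differentiation beyond what either deme holds internally.
#'
#' @inheritParams pairwise_between
#' @return Corrected pairwise difference; both demes need at least 2
#'   individuals.
#' @export
pairwise_corrected <- function(nA_x, na_x, nA_y, na_y) {
  pairwise_between(nA_x, na_x, nA_y, na_y) -
    (pairwise_within(nA_x, na_x) + pairwise_within(nA_y, na_y)) / 2
}

check_counts <- function(nA, na) {
  if (any(nA < 0) || any(na < 0) || any(!is.finite(nA)) || any(!is.finite(na)))
    stop("allele counts must be finite and non-negative", call. = FALSE)
  invisible(NULL)
}

#' Per-column front statistics
#'
#' Compute the eight per-column summaries of a frozen-record column: domain
#' and cline counts and mean widths from [segment_column()], the mean spectral
#' frequency from [mean_spectral_freq()], and the pairwise-difference
#' statistics aggregated over the column: `PX` is the unweighted mean of
#' [pairwise_within()] over the `N` demes, and `PXY` / `Pc` are unweighted
#' means of [pairwise_between()] / [pairwise_corrected()] over all
#' `choose(N, 2)` unordered deme pairs.
#'
#' @param nA,na Integer vectors of per-deme allele counts along the column
#'   (`N = length(nA)` demes, each with at least 2 individuals). For frozen
#'   records every deme holds exactly `K` individuals, so
#'   `nA = round(frequency * K)` and `na = K - nA`.
#' @param eps Fixation band forwarded to [segment_column()].
#' @return One-row data.frame with columns `n_domains`, `n_clines`,
#'   `mean_domain_width`, `mean_cline_width`, `PX`, `PXY`, `Pc`, `fbar`.
#' @examples
#' front_stats(nA = c(100, 100, 60, 0, 0), na = c(0, 0, 40, 100, 100))
#' @export
front_stats <- function(nA, na, eps = 0) {
  stopifnot(length(nA) == length(na), length(nA) >= 2)
  N <- length(nA)
  n <- nA + na
  if (any(n < 2)) stop("every deme needs at least 2 individuals", call. = FALSE)
  p <- nA / n
  seg <- segment_column(p, eps = eps)
  px <- pairwise_within(nA, na)

  # Means over all unordered deme pairs, in closed form:
  # sum_{i<j} [p_i(1-p_j) + p_j(1-p_i)] = (N-1)*S1 - (S1^2 - S2)
  s1 <- sum(p)
  s2 <- sum(p^2)
  n_pairs <- N * (N - 1) / 2
  pxy <- ((N - 1) * s1 - (s1^2 - s2)) / n_pairs
  # mean over pairs of (PX_i + PX_j)/2 equals mean(PX_i)
  pc <- pxy - mean(px)

  data.frame(
    n_domains = seg$n_domains, n_clines = seg$n_clines,
    mean_domain_width = seg$mean_domain_width,
    mean_cline_width = seg$mean_cline_width,
    PX = mean(px), PXY = pxy, Pc = pc,
    fbar = mean_spectral_freq(p)
  )
}

#' Front statistics for every recorded column of a run
#'
#' Applies [front_stats()] to each frozen-record column (and stationary
#' snapshot) of a simulation run. Counts are reconstructed from the recorded
#' frequencies as `nA = round(frequency * K)`, exact because every recorded
#' deme sits at carrying capacity.
#'
#' @param run A `sim_run` from [run_simulation()], or a long-format
#'   frozen-record table as produced by [frozen_records_table()] (in which
#'   case `K` must be given).
#' @param K Carrying capacity; taken from `run$params` when `run` is a
#'   `sim_run`.
#' @param eps Fixation band forwarded to [segment_column()].
#' @return Data.frame with one row per (replicate, recorded column):
#'   `replicate`, `column_index`, `generation_recorded`, then the
#'   [front_stats()] columns.
#' @export
front_stats_table <- function(run, K = NULL, eps = 0) {
  tab <- if (inherits(run, "sim_run")) {
    K <- run$params$K
    frozen_records_table(run)
  } else {
    stopifnot(is.data.frame(run), !is.null(K))
    run
  }
  if (!nrow(tab)) {
    return(data.frame(replicate = integer(0), column_index = integer(0),
                      generation_recorded = integer(0), n_domains = integer(0),
                      n_clines = integer(0), mean_domain_width = numeric(0),
                      mean_cline_width = numeric(0), PX = numeric(0),
                      PXY = numeric(0), Pc = numeric(0), fbar = numeric(0)))
  }
  key <- interaction(tab$replicate, tab$column_index, tab$generation_recorded,
                     drop = TRUE)
  pieces <- lapply(split(tab, key), function(d) {
    d <- d[order(d$row_index), ]
    nA <- as.integer(round(d$frequency * K))
    cbind(data.frame(replicate = d$replicate[1L],
                     column_index = d$column_index[1L],
                     generation_recorded = d$generation_recorded[1L]),
          front_stats(nA, K - nA, eps = eps))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$replicate, out$column_index, out$generation_recorded), ]
  rownames(out) <- NULL
  out
}
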