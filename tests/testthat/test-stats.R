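test_that("segmentation follows the domain/cline definitions", {
  s <- segment_column(c(1, 1, 1, 0.5, 0, 0))
  expect_equal(s$n_domains, 2)
  expect_equal(s$n_clines, 1)
  expect_equal(s$domains$width, c(3, 2))
  expect_equal(s$domains$allele, c("A", "a"))
  expect_equal(s$clines$width, 1)
  expect_equal(s$mean_domain_width, 2.5)

  # runs fixed for opposite alleles are distinct domains with no cline between
  s <- segment_column(c(1, 1, 0, 0))
  expect_equal(s$n_domains, 2)
  expect_equal(s$n_clines, 0)
  expect_true(is.na(s$mean_cline_width))

  s <- segment_column(rep(0.5, 9))
  expect_equal(s$n_domains, 0)
  expect_equal(s$n_clines, 1)
  expect_equal(s$clines$width, 9)

  expect_error(segment_column(numeric(0)))
  expect_error(segment_column(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("segmentation tiles the column and matches a brute-force scanner", {
  set.seed(14)
  for (i in 1:200) {
    N <- sample(c(5, 15, 75), 1)
    col <- random_column_counts(N, 100)
    freq <- col$nA / 100
    s <- segment_column(freq)
    expect_equal(sum(s$domains$width) + sum(s$clines$width), N)
    ref <- scan_segments(freq)
    expect_equal(s$n_domains + s$n_clines, length(ref))
    widths <- vapply(ref, function(x) x$width, numeric(1))
    labs <- vapply(ref, function(x) x$label, character(1))
    expect_equal(s$domains$width, widths[labs != "mixed"])
    expect_equal(s$clines$width, widths[labs == "mixed"])
  }
})

test_that("an eps fixation band reclassifies near-fixed demes", {
  freq <- c(0.99, 1, 0.5, 0.01, 0)
  expect_equal(segment_column(freq)$n_domains, 2)
  expect_equal(segment_column(freq, eps = 0.02)$n_domains, 2)
  expect_equal(segment_column(freq, eps = 0.02)$domains$width, c(2, 2))
})

test_that("the mean spectral frequency matches a direct DFT", {
  i <- 0:74
  # single cosine at wavenumber 5 over 75 demes -> fbar = 5/75
  p <- 0.5 + 0.4 * cos(2 * pi * 5 * i / 75)
  expect_equal(mean_spectral_freq(p), 5 / 75, tolerance = 1e-12)
  expect_equal(dft_fbar(p), 5 / 75, tolerance = 1e-9)

  # equal-amplitude wavenumbers 5 and 10 -> amplitude-weighted mean 0.1
  p2 <- 0.5 + 0.2 * cos(2 * pi * 5 * i / 75) + 0.2 * cos(2 * pi * 10 * i / 75)
  expect_equal(mean_spectral_freq(p2), 0.1, tolerance = 1e-12)

  expect_identical(mean_spectral_freq(rep(0.37, 75)), 0)
  expect_error(mean_spectral_freq(rep(0.5, 10)), "odd")

  set.seed(15)
  for (j in 1:50) {
    v <- runif(75)
    expect_equal(mean_spectral_freq(v), dft_fbar(v), tolerance = 1e-9)
  }
})

test_that("the mean spectral frequency stays inside its admissible band", {
  set.seed(16)
  N <- 75
  for (j in 1:50) {
    v <- round(runif(N, 0, 1) * 100) / 100
    f <- mean_spectral_freq(v)
    if (length(unique(v)) == 1) {
      expect_identical(f, 0)
    } else {
      expect_gte(f, 1 / N)
      expect_lte(f, (N - 1) / (2 * N))
    }
  }
  # alternating fixed columns fluctuate at the finest scale
  alt <- rep(c(1, 0), length.out = N)
  expect_gt(mean_spectral_freq(alt), 0.4)
})

test_that("pairwise difference statistics match pair enumeration", {
  expect_equal(pairwise_within(1, 1), 1)
  expect_equal(pairwise_within(100, 0), 0)
  expect_equal(pairwise_within(50, 50), 5000 / 9900)
  expect_equal(pairwise_within(50, 50), enum_within(50, 50))
  expect_error(pairwise_within(1, 0), "at least 2")

  expect_equal(pairwise_between(10, 0, 0, 10), 1)
  expect_equal(pairwise_between(50, 50, 50, 50), 0.5)
  expect_equal(pairwise_between(10, 0, 10, 0), 0)
  expect_error(pairwise_between(0, 0, 5, 5), "non-empty")

  expect_equal(pairwise_corrected(10, 0, 10, 0), 0)
  expect_equal(pairwise_corrected(10, 0, 0, 10), 1)
  expect_equal(pairwise_corrected(50, 50, 100, 0), 0.5 - (5000 / 9900) / 2)

  set.seed(17)
  for (j in 1:100) {
    nx <- sample(2:12, 2, replace = TRUE)
    ax <- sample(0:nx[1], 1); ay <- sample(0:nx[2], 1)
    expect_equal(pairwise_within(ax, nx[1] - ax), enum_within(ax, nx[1] - ax))
    expect_equal(pairwise_between(ax, nx[1] - ax, ay, nx[2] - ay),
                 enum_between(ax, nx[1] - ax, ay, nx[2] - ay))
    expect_equal(pairwise_corrected(ax, nx[1] - ax, ay, nx[2] - ay),
                 enum_corrected(ax, nx[1] - ax, ay, nx[2] - ay))
  }
})

test_that("front statistics aggregate the per-deme and per-pair means", {
  # monomorphic column: one domain, everything else zero
  fs <- front_stats(rep(100L, 9), rep(0L, 9))
  expect_equal(fs$n_domains, 1)
  expect_equal(fs$mean_domain_width, 9)
  expect_equal(fs$PX, 0); expect_equal(fs$PXY, 0); expect_equal(fs$Pc, 0)
  expect_identical(fs$fbar, 0)

  # uniform 0.5 column: one cline, PX ~ 0.50505, slightly negative Pc
  fs <- front_stats(rep(50L, 9), rep(50L, 9))
  expect_equal(fs$n_clines, 1)
  expect_equal(fs$PX, 5000 / 9900)
  expect_lt(fs$Pc, 0)

  # PXY/Pc equal the explicit mean over all unordered deme pairs
  set.seed(18)
  K <- 30L
  nA <- as.integer(rbinom(7, K, runif(7)))
  fs <- front_stats(nA, K - nA)
  pairs <- utils::combn(7, 2)
  pxy <- mean(apply(pairs, 2, function(ij)
    pairwise_between(nA[ij[1]], K - nA[ij[1]], nA[ij[2]], K - nA[ij[2]])))
  pc <- mean(apply(pairs, 2, function(ij)
    pairwise_corrected(nA[ij[1]], K - nA[ij[1]], nA[ij[2]], K - nA[ij[2]])))
  expect_equal(fs$PXY, pxy)
  expect_equal(fs$Pc, pc)
})

test_that("permuting demes leaves PX/PXY/Pc invariant but moves segmentation and fbar", {
  set.seed(19)
  K <- 100L
  col <- random_column_counts(15, K)
  ord <- sample(15)
  a <- front_stats(col$nA, col$na)
  b <- front_stats(col$nA[ord], col$na[ord])
  expect_equal(a$PX, b$PX)
  expect_equal(a$PXY, b$PXY)
  expect_equal(a$Pc, b$Pc)
  # position-sensitive statistics generally change under permutation
  diffs <- replicate(20, {
    o <- sample(15)
    c(front_stats(col$nA[o], col$na[o])$fbar,
      front_stats(col$nA[o], col$na[o])$n_domains)
  })
  expect_gt(length(unique(round(diffs[1, ], 12))), 1)
})

test_that("front_stats_table reconstructs counts from frozen frequencies", {
  run <- run_simulation(small_test_params(seed = 20))
  tab <- front_stats_table(run)
  expect_named(tab, c("replicate", "column_index", "generation_recorded",
                      "n_domains", "n_clines", "mean_domain_width",
                      "mean_cline_width", "PX", "PXY", "Pc", "fbar"))
  expect_equal(tab$column_index, 6:30)
  expect_true(all(tab$PX >= 0 & tab$PX <= 1))
  expect_true(all(tab$PXY >= 0 & tab$PXY <= 1))

  # recomputing from the long table gives identical rows
  long <- frozen_records_table(run)
  tab2 <- front_stats_table(long, K = run$params$K)
  expect_equal(tab, tab2, tolerance = 1e-12)

  # one spot-check against front_stats on the raw column
  j <- tab$column_index[10]
  nA <- as.integer(round(run$freq[, j] * run$params$K))
  expect_equal(unlist(tab[10, 4:11]),
               unlist(front_stats(nA, run$params$K - nA)),
               ignore_attr = TRUE)
})
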