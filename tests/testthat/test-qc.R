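test_that("neighbour-difference MAD matches the closed form", {
  b <- flat_bins(101)
  expect_equal(compute_mad(rep(1, 101), b), 0)
  # 101 bins -> 100 differences, an even split of +0.4 / -0.4 whose
  # median is 0, so every |d - median| is 0.4
  alt <- rep_len(c(0.8, 1.2), 101)
  expect_equal(compute_mad(alt, b), 0.4 * 1.4826, tolerance = 1e-9)
  expect_error(compute_mad(c(1, 1), flat_bins(2)), "3 autosomal bins")
})

test_that("MAD ignores shifts, scales with amplitude, skips chromosome joins", {
  b <- flat_bins(101)
  alt <- rep_len(c(0.8, 1.2), 101)
  expect_equal(compute_mad(alt + 5, b), compute_mad(alt, b))
  expect_equal(compute_mad(1 + 3 * (alt - 1), b),
               3 * compute_mad(alt, b), tolerance = 1e-9)
  # a level shift between chromosomes contributes no difference pair
  b2 <- build_bins(c(chr1 = 2.5e6, chr2 = 2.5e6), "fixed", 250e3)
  x <- c(rep(1, 10), rep(2, 10))
  expect_equal(compute_mad(x, b2), 0)
})

test_that("MAD is robust to an abrupt copy-number change", {
  set.seed(9)
  b <- flat_bins(5000)
  x <- exp(rnorm(5000, 0, 0.1))
  with_cnv <- x
  with_cnv[2001:2010] <- with_cnv[2001:2010] * 2   # 10-bin CN 4 event
  expect_lt(abs(compute_mad(with_cnv, b) / compute_mad(x, b) - 1), 0.05)
})

test_that("Lorenz curve and Gini behave at the extremes", {
  lc <- lorenz_curve(rep(2, 50))
  expect_equal(lc$gini, 0)
  expect_equal(lc$read_frac, lc$genome_frac)

  n <- 40
  one <- c(rep(0, n - 1), 100)
  expect_equal(lorenz_curve(one)$gini, (n - 1) / n)
  expect_error(lorenz_curve(rep(0, 5)), "all-zero")
})

test_that("Gini never decreases under a mean-preserving spread", {
  set.seed(10)
  x <- rgamma(200, 4)
  g0 <- lorenz_curve(x)$gini
  for (k in 1:20) {
    y <- x
    ij <- sample(200, 2)
    i <- ij[which.min(x[ij])]; j <- ij[which.max(x[ij])]
    t <- 0.5 * min(y[i], 1)
    y[i] <- y[i] - t; y[j] <- y[j] + t   # transfer poor -> rich
    expect_gte(lorenz_curve(y)$gini, g0 - 1e-12)
  }
})

test_that("confidence score rewards integer copy numbers", {
  seg <- function(cn, nb) data.frame(chrom = "chr1", n_bins = nb, cn_est = cn)
  expect_equal(confidence_score(seg(c(2, 3, 1), c(10, 5, 5))), 1)
  expect_equal(confidence_score(seg(2.5, 10)), 0)
  expect_equal(confidence_score(seg(c(2, 2.25), c(10, 10))), 0.75)
  empty <- data.frame(chrom = character(), n_bins = integer(),
                      cn_est = numeric())
  expect_error(confidence_score(empty), "empty|no aut")
})

test_that("the QC gate keeps boundary values", {
  expect_true(qc_gate(0.15, 0.9))
  expect_false(qc_gate(0.31, 0.9))
  expect_true(qc_gate(0.3, 0.7))
  expect_false(qc_gate(0.2, 0.69))
})
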