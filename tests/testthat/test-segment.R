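test_that("a constant profile yields a single segment per chromosome", {
  b <- flat_bins(60)
  ss <- cbs_segment(rep(1, 60), b, rng_seed = 1)
  expect_equal(nrow(ss$segments), 1L)
  expect_equal(ss$segments$n_bins, 60L)

  b2 <- build_bins(c(chr1 = 2.5e6, chr2 = 2.5e6), "fixed", 250e3)
  ss2 <- cbs_segment(rep(1, 20), b2, rng_seed = 1)
  expect_equal(nrow(ss2$segments), 2L)  # one per chromosome
})

test_that("a short chromosome stays unsplit", {
  b <- flat_bins(8)
  x <- c(rep(1, 4), rep(2, 4))
  ss <- cbs_segment(x, b, min_width = 5, rng_seed = 1)
  expect_equal(nrow(ss$segments), 1L)
})

test_that("a planted step is found within two bins", {
  set.seed(22)
  b <- flat_bins(150)
  x <- c(rnorm(100, 1, 0.1), rnorm(50, 1.5, 0.1))
  ss <- cbs_segment(x, b, rng_seed = 3)
  expect_equal(nrow(ss$segments), 2L)
  expect_lte(abs(ss$segments$end_bin[1] - 100), 2)
})

test_that("the accepted arc equals the brute-force maximal-statistic arc", {
  set.seed(23)
  for (case in 1:12) {
    n <- sample(20:60, 1)
    x <- rnorm(n, 1, 0.1)
    lo <- sample(seq(5, n - 10), 1)
    hi <- min(n, lo + sample(5:15, 1))
    x[lo:hi] <- x[lo:hi] + sample(c(-0.5, 0.5), 1)
    fast <- cbs_best_arc(x, 5)
    slow <- brute_best_arc(x, 5)
    expect_equal(fast$stat, slow$stat, tolerance = 1e-12)
    expect_equal(fast$i, slow$i)
    expect_equal(fast$j, slow$j)
  }
})

test_that("segmentation is deterministic given the seed", {
  set.seed(24)
  b <- flat_bins(200)
  x <- c(rnorm(80, 1, 0.12), rnorm(40, 1.5, 0.12), rnorm(80, 1, 0.12))
  s1 <- cbs_segment(x, b, rng_seed = 7)
  s2 <- cbs_segment(x, b, rng_seed = 7)
  expect_identical(s1, s2)
})

test_that("ploidy fitting maps ratio clusters to integers", {
  seg <- function(mr, nb) data.frame(chrom = "chr1", n_bins = nb,
                                     mean_ratio = mr)
  expect_equal(fit_ploidy(seg(1, 100)), 2)
  expect_equal(fit_ploidy(seg(c(1, 1.5), c(90, 10))), 2)
  expect_equal(fit_ploidy(seg(c(1, 4 / 3, 2 / 3), c(10, 10, 10))), 3)
  expect_error(fit_ploidy(seg(1, 10), grid = numeric(0)), "grid")
})

test_that("thresholds fall in the gaps between copy-number modes", {
  expect_equal(derive_thresholds(NULL, derive = FALSE),
               c(loss = 1.29, gain = 2.80))

  set.seed(25)
  seg <- data.frame(chrom = "chr1", n_bins = 10,
                    cn_est = c(rnorm(40, 1, 0.1), rnorm(200, 2, 0.1),
                               rnorm(40, 3, 0.1)))
  thr <- derive_thresholds(seg)
  expect_gt(thr[["loss"]], 1.3); expect_lt(thr[["loss"]], 1.9)
  expect_gt(thr[["gain"]], 2.1); expect_lt(thr[["gain"]], 2.9)

  flat <- data.frame(chrom = "chr1", n_bins = 10, cn_est = rep(2, 50))
  thr2 <- derive_thresholds(flat)
  expect_equal(unname(thr2), c(1.5, 2.5))

  few <- data.frame(chrom = "chr1", n_bins = 10, cn_est = rep(2, 5))
  expect_warning(thr3 <- derive_thresholds(few), "fewer than 20")
  expect_equal(thr3, c(loss = 1.29, gain = 2.80))
})

test_that("segment-size eligibility bounds the threshold pool", {
  set.seed(26)
  good <- data.frame(chrom = "chr1", n_bins = 10,
                     cn_est = c(rnorm(30, 1, 0.05), rnorm(100, 2, 0.05),
                                rnorm(30, 3, 0.05)))
  decoys <- data.frame(chrom = "chr1", n_bins = c(rep(2, 30), rep(500, 30)),
                       cn_est = rep(c(1.45, 2.55), 30))
  thr <- derive_thresholds(rbind(good, decoys))
  # decoys sit just inside the mode gaps; were they pooled, the loss
  # threshold would be dragged to ~1.66 and the gain one to ~2.34
  expect_lt(thr[["loss"]], 1.6)
  expect_gt(thr[["gain"]], 2.4)
})

test_that("call extraction applies thresholds and the size floor", {
  seg <- data.frame(chrom = "chr1", start = c(0, 10e6, 20e6),
                    end = c(10e6, 20e6, 21.5e6),
                    n_bins = c(10L, 6L, 4L),
                    mean_ratio = c(1.395, 1.55, 0.6),
                    cn_est = c(2.79, 3.1, 1.2),
                    cn_int = c(3L, 3L, 1L))
  calls <- extract_cnvs(seg, cell_id = "c1")
  expect_equal(nrow(calls), 1L)        # 2.79 < 2.80; 4 bins too small
  expect_equal(calls$type, "gain")
  expect_equal(calls$cn_int, 3L)

  seg$cn_est[1] <- 2.80
  expect_equal(nrow(extract_cnvs(seg)), 2L)  # boundary value calls
})

test_that("male cells call chrX at copy number 1 and autosomes at 2", {
  cells <- data.frame(cell_id = c("M1", "M2"), individual_id = "I1",
                      method = "picoplex", sex = "male")
  spec <- cohort_spec(cells, genome = c(chr1 = 30e6, chrX = 20e6),
                      cnv_menu = NULL, rng_seed = 41)
  sim <- simulate_cohort(spec)
  for (i in 1:2) {
    p <- cell_profile(cells$cell_id[i], sim$counts[, i], sim$bins)
    res <- call_cell(p, rng_seed = i)
    seg <- res$segments$segments
    expect_true(all(seg$cn_int[seg$chrom == "chrX"] == 1L))
    expect_true(all(seg$cn_int[seg$chrom == "chr1"] == 2L))
  }
})
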