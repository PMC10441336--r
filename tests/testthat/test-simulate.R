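test_that("the noise-free limit returns exact expected counts", {
  cells <- small_cohort(2)
  spec <- cohort_spec(cells, genome = c(chr1 = 5e6), bin_size = 250e3,
                      mean_reads_per_bin = 100, cnv_menu = NULL)
  prof <- list(picoplex = wga_profile("picoplex", bin_noise_sd = 0))
  sim <- simulate_cohort(spec, prof)
  expect_true(all(sim$counts == 100L))
})

test_that("simulation is deterministic and independent of cell order", {
  cells <- small_cohort(4)
  spec <- cohort_spec(cells, genome = c(chr1 = 10e6), rng_seed = 21)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)

  rev_cells <- cells[rev(seq_len(nrow(cells))), ]
  s3 <- simulate_cohort(cohort_spec(rev_cells, genome = c(chr1 = 10e6),
                                    rng_seed = 21))
  expect_identical(s1$counts[, "C02"], s3$counts[, "C02"])
})

test_that("planted events scale expected depth by cn/2", {
  cells <- small_cohort(1)
  menu <- data.frame(size_bp = 3e6, cn = 3L, frequency = 1)
  spec <- cohort_spec(cells, genome = c(chr1 = 30e6), bin_size = 250e3,
                      mean_reads_per_bin = 400, cnv_menu = menu,
                      rng_seed = 5)
  sim <- simulate_cohort(spec, quiet_profiles(0.02))
  tr <- sim$truth
  expect_equal(nrow(tr), 1L)
  inside <- sim$bins$start >= tr$start & sim$bins$end <= tr$end
  expect_equal(mean(sim$counts[inside, 1]) / mean(sim$counts[!inside, 1]),
               1.5, tolerance = 0.05)
})

test_that("expected total depth is conserved without dropout", {
  cells <- small_cohort(1)
  totals <- vapply(1:20, function(s) {
    spec <- cohort_spec(cells, genome = c(chr1 = 10e6), bin_size = 250e3,
                        mean_reads_per_bin = 200, cnv_menu = NULL,
                        rng_seed = s)
    sum(simulate_cohort(spec, quiet_profiles(0.1))$counts)
  }, numeric(1))
  n_bins <- 40
  expected <- 200 * n_bins
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se + 1e-9)
})

test_that("cohort MAD is non-decreasing in the bin noise scale", {
  cells <- small_cohort(5)
  mean_mad <- function(sd) {
    spec <- cohort_spec(cells, genome = c(chr1 = 25e6), cnv_menu = NULL,
                        rng_seed = 31)
    sim <- simulate_cohort(spec, quiet_profiles(sd))
    mean(apply(sim$counts, 2, function(r)
      compute_mad(normalize_counts(r, sim$bins), sim$bins)))
  }
  m <- vapply(c(0.05, 0.2, 0.5), mean_mad, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("default chemistry profiles hit the published evenness scores", {
  mean_mad <- function(method) {
    cells <- small_cohort(20, method = method, prefix = toupper(method))
    spec <- cohort_spec(cells, cnv_menu = NULL, rng_seed = 1)
    sim <- simulate_cohort(spec)
    mean(vapply(seq_len(20), function(i) {
      p <- cell_profile(cells$cell_id[i], sim$counts[, i], sim$bins)
      compute_mad(p$corrected, sim$bins)
    }, numeric(1)))
  }
  m_pico <- mean_mad("picoplex")
  m_dmda <- mean_mad("dmda")
  expect_gt(m_pico, 0.10); expect_lt(m_pico, 0.20)
  expect_gt(m_dmda, 0.45); expect_lt(m_dmda, 0.70)
})

test_that("higher-noise chemistries produce higher Gini", {
  gini_of <- function(method) {
    cells <- small_cohort(8, method = method, prefix = toupper(method))
    spec <- cohort_spec(cells, genome = c(chr1 = 40e6), cnv_menu = NULL,
                        rng_seed = 2)
    sim <- simulate_cohort(spec)
    mean(apply(sim$counts, 2, function(r)
      lorenz_curve(normalize_counts(r, sim$bins))$gini))
  }
  expect_gt(gini_of("dmda"), gini_of("picoplex"))
})

test_that("unknown method labels are a configuration error", {
  spec <- cohort_spec(small_cohort(2, method = "malbac"))
  expect_error(simulate_cohort(spec), "no profile")
})

test_that("pair simulation honours its mixture and labels truthfully", {
  expect_equal(nrow(simulate_pairs(0, c(inward = 1))), 0L)

  p <- simulate_pairs(200, c(inward = 1), rng_seed = 4)
  expect_true(all(classify_pairs(p) == "inward"))

  expect_error(simulate_pairs(10, c(inward = -0.5, outward = 1.5)),
               "negative")

  mix <- c(outward = 0.5, interchrom = 0.5)
  s <- summarize_chimeras(simulate_pairs(10000, mix, rng_seed = 8))
  expect_lt(abs(s$fractions["outward"] - 0.5), 0.02)
  expect_lt(abs(s$fractions["interchrom"] - 0.5), 0.02)

  p4 <- simulate_pairs(2000, c(inward = 0.4, outward = 0.3,
                               interchrom = 0.2, other = 0.1), rng_seed = 12)
  expect_equal(classify_pairs(p4), p4$category)
})
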