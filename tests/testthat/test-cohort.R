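test_that("Fisher exact matches full hypergeometric enumeration", {
  # exhaustive over all tables with N <= 12, random draws up to N = 40
  for (N in 2:12) {
    for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
      d <- N - a - b - c
      tab <- matrix(c(a, c, b, d), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab), brute_fisher(tab), tolerance = 1e-9)
    }
  }
  set.seed(35)
  for (k in 1:200) {
    tab <- matrix(rmultinom(1, sample(13:40, 1), runif(4, 0.05, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), brute_fisher(tab), tolerance = 1e-9)
  }
})

test_that("printed group comparisons are reproduced from printed counts", {
  # 8/23 PicoPLEX v 6/11 PTA cells with CNVs
  expect_equal(fisher_exact(matrix(c(8, 6, 15, 5), 2)), 0.46,
               tolerance = 0.005 / 0.46)
  # 10/24 MSA v 3/10 control
  expect_equal(fisher_exact(matrix(c(10, 3, 14, 7), 2)), 0.70,
               tolerance = 0.01 / 0.70)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-9)
  expect_warning(p <- fisher_exact(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_equal(p, 1)
})

test_that("rank-sum p-values match exact enumeration and symmetry", {
  expect_equal(rank_sum(c(1, 2, 3), c(10, 11, 12)), 0.1, tolerance = 1e-9)
  expect_equal(rank_sum(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 0.01)
  set.seed(36)
  a <- rnorm(8); b <- sample(a)
  expect_equal(rank_sum(a, b), 1, tolerance = 0.02)
  expect_error(rank_sum(numeric(0), 1), "two observations")
})

test_that("cohort roll-up reproduces the published arithmetic", {
  r <- cohort_rollup(n_passed = 34, n_cnv_cells = 13, n_calls = 36,
                     n_gains = 23)
  expect_equal(r$cnv_cell_pct, 38.2, tolerance = 0.002)
  expect_equal(r$gain_pct, 63.9, tolerance = 0.001)
  expect_equal(r$mean_calls_per_cnv_cell, 2.8, tolerance = 0.02)
  expect_equal(r$total_calls, 36)
})

test_that("the summary table aggregates per individual and method", {
  manifest <- data.frame(cell_id = c("a", "b", "c", "d"),
                         individual_id = c("I1", "I1", "I1", "I2"),
                         method = c("picoplex", "picoplex", "pta", "pta"))
  qc <- data.frame(cell_id = manifest$cell_id,
                   passes = c(TRUE, TRUE, FALSE, TRUE))
  calls <- data.frame(cell_id = c("a", "a"), type = c("gain", "gain"))
  tab <- summarize_cohort(qc, calls, manifest)
  row <- tab[tab$individual_id == "I1" & tab$method == "picoplex", ]
  expect_equal(row$n_passed, 2L)
  expect_equal(row$cnv_cell_pct, 50)
  expect_equal(row$gains, 2L)
  roll <- attr(tab, "rollup")
  expect_equal(roll$mean_calls_per_cnv_cell, 2)
  expect_equal(roll$total_calls, 2L)

  empty <- summarize_cohort(qc, data.frame(cell_id = character(),
                                           type = character()), manifest)
  expect_true(all(empty$total_calls == 0))

  one <- summarize_cohort(
    data.frame(cell_id = "a", passes = TRUE),
    data.frame(cell_id = c("a", "a"), type = c("gain", "gain")),
    data.frame(cell_id = "a", individual_id = "I1", method = "picoplex"))
  expect_equal(one$cnv_cell_pct, 100)
  expect_equal(attr(one, "rollup")$mean_calls_per_cnv_cell, 2)
})

test_that("recovery evaluation scores overlap-matched calls", {
  truth <- data.frame(cell_id = "a", chrom = "chr1", start = 10e6,
                      end = 20e6, cn = 3)
  hit <- data.frame(cell_id = "a", chrom = "chr1", start = 9.5e6,
                    end = 19e6, type = "gain")
  miss <- data.frame(cell_id = "a", chrom = "chr1", start = 30e6,
                     end = 40e6, type = "gain")
  r <- evaluate_recovery(rbind(hit, miss), truth)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 0.5)
})
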