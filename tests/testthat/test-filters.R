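mk_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), type = r[[4]], cell_id = r[[5]],
               individual_id = r[[6]], method = r[[7]],
               cn_int = if (r[[4]] == "gain") 3L else 1L,
               cn_est = if (r[[4]] == "gain") 3 else 1, n_bins = 10L)))
}

test_that("sharing links calls within the method tolerance", {
  calls <- mk_calls(
    list("chr1", 10e6, 20e6, "gain", "a", "I1", "picoplex"),
    list("chr1", 10e6, 20e6, "gain", "b", "I1", "picoplex"),
    list("chr1", 12.4e6, 22.4e6, "gain", "c", "I1", "picoplex"),
    list("chr1", 15.1e6, 22.4e6, "gain", "d", "I1", "picoplex"))
  g <- match_shared(calls)$group
  expect_equal(g[1], g[2])   # identical calls share a group
  expect_equal(g[1], g[3])   # 2.4 Mb offsets link for PicoPLEX
  expect_false(g[4] == g[1]) # 2.7 Mb start offset does not link directly...
  calls2 <- calls[c(1, 4), ]
  expect_false(match_shared(calls2)$group[1] ==
                 match_shared(calls2)$group[2])
})

test_that("sharing is transitive and uses the larger mixed-method tolerance", {
  chain <- mk_calls(
    list("chr2", 10e6, 20e6, "loss", "a", "I1", "picoplex"),
    list("chr2", 12e6, 22e6, "loss", "b", "I1", "picoplex"),
    list("chr2", 14e6, 24e6, "loss", "c", "I1", "picoplex"))
  expect_equal(length(unique(match_shared(chain)$group)), 1L)

  mixed <- mk_calls(
    list("chr3", 10e6, 20e6, "gain", "a", "I1", "picoplex"),
    list("chr3", 14e6, 24e6, "gain", "b", "I1", "pta"))
  expect_equal(length(unique(match_shared(mixed)$group)), 1L)  # 4 Mb <= 5 Mb
})

test_that("calls on different chromosomes or of different types never group", {
  calls <- mk_calls(
    list("chr1", 10e6, 20e6, "gain", "a", "I1", "picoplex"),
    list("chr2", 10e6, 20e6, "gain", "b", "I1", "picoplex"),
    list("chr1", 10e6, 20e6, "loss", "c", "I1", "picoplex"))
  expect_equal(length(unique(match_shared(calls)$group)), 3L)
})

test_that("grouping is invariant to input order", {
  set.seed(31)
  calls <- mk_calls(
    list("chr1", 10e6, 20e6, "gain", "a", "I1", "picoplex"),
    list("chr1", 11e6, 21e6, "gain", "b", "I1", "picoplex"),
    list("chr1", 30e6, 40e6, "gain", "c", "I1", "picoplex"),
    list("chr2", 10e6, 20e6, "loss", "d", "I1", "picoplex"),
    list("chr2", 11e6, 21e6, "loss", "e", "I2", "pta"))
  partition <- function(df) {
    g <- match_shared(df)
    unname(vapply(split(g$cell_id, g$group),
                  function(v) paste(sort(v), collapse = ","), ""))
  }
  parts0 <- partition(calls)
  for (k in 1:5) {
    perm <- calls[sample(nrow(calls)), ]
    expect_setequal(partition(perm), parts0)
  }
})

test_that("artifact filtering drops recurrent and cross-individual groups", {
  shared <- do.call(rbind, lapply(sprintf("c%02d", 1:12), function(id)
    mk_calls(list("chr1", 10e6, 20e6, "gain", id, "I1", "picoplex"))))
  cross <- mk_calls(
    list("chr2", 5e6, 15e6, "loss", "m1", "MSA1", "picoplex"),
    list("chr2", 5e6, 15e6, "loss", "k1", "Control", "picoplex"))
  private <- mk_calls(list("chr3", 5e6, 15e6, "gain", "c01", "I1", "picoplex"))
  calls <- match_shared(rbind(shared, cross, private))
  kept <- filter_artifacts(calls, list(I1 = 23, MSA1 = 10, Control = 10))
  expect_equal(kept$chrom, "chr3")   # 12/23 >= half dropped; cross dropped
  expect_equal(kept$cell_id, "c01")

  # 11 shared calls (11/23 < half) plus c01's private call all survive
  kept2 <- filter_artifacts(calls[calls$cell_id %in%
                                    sprintf("c%02d", 1:11), , drop = FALSE],
                            list(I1 = 23))
  expect_equal(nrow(kept2), 12L)
})

test_that("sub-telomeric flags fire only near chromosome ends", {
  calls <- mk_calls(
    list("chr1", 0, 5e6, "gain", "a", "I1", "picoplex"),
    list("chr1", 20e6, 30e6, "gain", "b", "I1", "picoplex"),
    list("chr1", 44e6, 49.9e6, "loss", "c", "I1", "picoplex"))
  out <- annotate_subtelomeric(calls, c(chr1 = 50e6), window_bp = 500e3)
  expect_equal(out$subtelomeric, c(TRUE, FALSE, TRUE))
})

test_that("novel-region selection uses union overlap of at least half", {
  novel <- data.frame(chrom = "chr1",
                      start = c(10e6, 16e6), end = c(14e6, 40e6))
  calls <- mk_calls(
    list("chr1", 11e6, 13e6, "gain", "a", "I1", "picoplex"),  # fully inside
    list("chr1", 0, 10e6, "gain", "b", "I1", "picoplex"),     # 0 %
    list("chr1", 12e6, 17e6, "gain", "c", "I1", "picoplex"),  # 3/5 via union
    list("chr1", 13e6, 18e6, "gain", "d", "I1", "picoplex"))  # 3/5 via union
  kept <- novel_region_gains(calls, novel)
  expect_setequal(kept$cell_id, c("a", "c", "d"))

  forty <- mk_calls(list("chr1", 12e6, 17e6, "gain", "e", "I1", "picoplex"))
  novel2 <- data.frame(chrom = "chr1", start = 10e6, end = 14e6)
  expect_equal(nrow(novel_region_gains(forty, novel2)), 0L)  # 2/5 dropped

  expect_error(novel_region_gains(calls,
                                  data.frame(chrom = "chr1", start = 5,
                                             end = 2)), "malformed")
})

test_that("near-complete chromosome coverage is promoted to aneusomy", {
  lens <- c(chr13 = 100e6)
  two_losses <- mk_calls(
    list("chr13", 0, 60e6, "loss", "a", "I1", "picoplex"),
    list("chr13", 62.3e6, 100e6, "loss", "a", "I1", "picoplex"))
  res <- aneusomy_check(two_losses, lens)
  expect_equal(nrow(res$aneusomies), 1L)
  expect_equal(res$aneusomies$type, "loss")
  expect_equal(res$calls$start, 0)
  expect_equal(res$calls$end, 100e6)

  half <- mk_calls(list("chr13", 0, 50e6, "loss", "a", "I1", "picoplex"))
  expect_equal(nrow(aneusomy_check(half, lens)$aneusomies), 0L)

  whole_gain <- mk_calls(list("chr13", 0, 100e6, "gain", "a", "I1", "picoplex"))
  res3 <- aneusomy_check(whole_gain, lens)
  expect_equal(res3$aneusomies$type, "gain")
})
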