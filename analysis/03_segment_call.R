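#!/usr/bin/env Rscript
# Read-depth segmentation and integer copy-number calling for the cells
# passing QC (PicoPLEX at 250 kb, PTA at 500 kb): circular binary
# segmentation (alpha = 0.01, min width 5), ploidy fitting, gain/loss
# calls at the 1.29 / 2.80 thresholds, minimum 5 bins. Also derives the
# thresholds from the pooled segment copy numbers for comparison with the
# configured defaults. Writes results/calls_unfiltered.bed and
# results/segments.tsv.

library(scwgacnv)

manifest <- read.delim("results/cohort/manifest.tsv")
qc <- read.delim("results/qc.tsv")
passed <- qc$cell_id[qc$passes]

calls <- list(); segs <- list()
for (m in c("picoplex", "pta")) {
  counts <- read.delim(file.path("results/cohort",
                                 paste0("counts_", m, ".tsv")),
                       check.names = FALSE)
  bins <- counts[c("chrom", "start", "end")]
  bins$gc <- NA_real_; bins$mappability <- 1
  class(bins) <- c("bin_scheme", "data.frame")
  mc <- manifest[manifest$method == m & manifest$cell_id %in% passed, ]
  for (i in seq_len(nrow(mc))) {
    prof <- cell_profile(mc$cell_id[i], counts[[mc$cell_id[i]]], bins,
                         mc$individual_id[i], m)
    res <- call_cell(prof, rng_seed = i)
    calls[[length(calls) + 1L]] <- res$calls
    sg <- res$segments$segments
    sg$cell_id <- mc$cell_id[i]
    segs[[length(segs) + 1L]] <- sg
  }
}
calls <- do.call(rbind, calls)
segs <- do.call(rbind, segs)

write.table(segs, "results/segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_calls_bed(calls, "results/calls_unfiltered.bed")

thr <- derive_thresholds(segs)
message(sprintf("segments: %d across %d cells; %d raw calls",
                nrow(segs), length(unique(segs$cell_id)), nrow(calls)))
message(sprintf("data-derived thresholds: loss %.2f / gain %.2f ",
                thr[["loss"]], thr[["gain"]]),
        "(configured defaults 1.29 / 2.80)")
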