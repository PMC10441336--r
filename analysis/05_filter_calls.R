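#!/usr/bin/env Rscript
# Multi-cell artifact filtering and annotation of the raw calls: group
# recurrent calls (2.5 Mb tolerance for PicoPLEX, 5 Mb for PTA), drop
# groups spanning >= half of an individual's passed cells or more than
# one individual, flag sub-telomeric calls, promote near-complete
# chromosome coverage to aneusomies, and score recovery against the
# simulation ground truth. Writes results/calls_filtered.bed.

library(scwgacnv)

manifest <- read.delim("results/cohort/manifest.tsv")
qc <- read.delim("results/qc.tsv")
raw <- read.delim("results/calls_unfiltered.bed", header = FALSE,
                  col.names = c("chrom", "start", "end", "cell_id",
                                "cn_int", "type", "n_bins", "cn_est"))
raw <- merge(raw, manifest, by = "cell_id")

grouped <- match_shared(raw)
n_passed <- table(merge(qc[qc$passes, ], manifest)$individual_id)
kept <- filter_artifacts(grouped, as.list(n_passed))

genome <- setNames(rep(100e6, 8), paste0("chr", 1:8))
kept <- annotate_subtelomeric(kept, genome)
an <- aneusomy_check(kept, genome)
kept <- an$calls

write_calls_bed(kept, "results/calls_filtered.bed")

truth <- do.call(rbind, lapply(c("picoplex", "pta"), function(m)
  read.delim(file.path("results/cohort", paste0("truth_", m, ".tsv")))))
truth <- truth[truth$cell_id %in% qc$cell_id[qc$passes], ]
rec <- evaluate_recovery(kept, truth)

message(sprintf("%d raw calls -> %d after artifact filtering", nrow(raw),
                nrow(kept)))
message(sprintf("%d sub-telomeric (%.1f%%), %d whole-chromosome aneusomies",
                sum(kept$subtelomeric),
                100 * mean(kept$subtelomeric), nrow(an$aneusomies)))
message(sprintf("recovery vs ground truth: recall %.2f, precision %.2f",
                rec$recall, rec$precision))
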