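#!/usr/bin/env Rscript
# Cohort roll-up: per individual x method QC pass rates, CNV-bearing cell
# fractions and call counts, with the group-comparison statistics used in
# the study (Fisher exact between chemistries and disease groups,
# Mann-Whitney on call sizes). Writes results/summary.tsv.

library(scwgacnv)

manifest <- read.delim("results/cohort/manifest.tsv")
qc <- read.delim("results/qc.tsv")
calls <- read.delim("results/calls_filtered.bed", header = FALSE,
                    col.names = c("chrom", "start", "end", "cell_id",
                                  "cn_int", "type", "n_bins", "cn_est"))

summary <- summarize_cohort(qc, calls, manifest)
write.table(summary, "results/summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(summary, row.names = FALSE)

roll <- attr(summary, "rollup")
message(sprintf(
  "cohort: %.1f%% of passed cells carry >= 1 CNV; %.1f%% of %d calls are gains; mean %.1f calls per CNV cell",
  roll$cnv_cell_pct, roll$gain_pct, roll$total_calls,
  roll$mean_calls_per_cnv_cell))

qcm <- merge(qc[qc$passes, ], manifest)
cnv_cells <- unique(calls$cell_id)
by_m <- sapply(split(qcm$cell_id, qcm$method),
               function(ids) c(with_cnv = sum(ids %in% cnv_cells),
                               without = sum(!ids %in% cnv_cells)))
if (all(c("picoplex", "pta") %in% colnames(by_m))) {
  p <- fisher_exact(t(by_m[, c("picoplex", "pta")]))
  message(sprintf("PicoPLEX vs PTA CNV-cell fraction: Fisher p = %.2f", p))
}
sizes <- (calls$end - calls$start) / 1e6
mtd <- manifest$method[match(calls$cell_id, manifest$cell_id)]
if (length(unique(mtd)) == 2) {
  message(sprintf(
    "call sizes: median %.2f Mb (PicoPLEX) vs %.2f Mb (PTA), Mann-Whitney p = %.2f",
    median(sizes[mtd == "picoplex"]), median(sizes[mtd == "pta"]),
    rank_sum(sizes[mtd == "picoplex"], sizes[mtd == "pta"])))
}
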