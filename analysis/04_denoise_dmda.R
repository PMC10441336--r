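#!/usr/bin/env Rscript
# PCA denoising of the dMDA cells at 1 Mb bins: sweep the 40-90% shared-
# variance grid and report the cohort MAD trajectory. dMDA read depth is
# too uneven for direct calling; denoising removes the recurrent
# component and is the route by which very large aberrations become
# callable. Writes results/denoise_mad.tsv.

library(scwgacnv)

manifest <- read.delim("results/cohort/manifest.tsv")
counts <- read.delim("results/cohort/counts_dmda.tsv", check.names = FALSE)
bins <- counts[c("chrom", "start", "end")]
bins$gc <- NA_real_; bins$mappability <- 1
class(bins) <- c("bin_scheme", "data.frame")

mc <- manifest[manifest$method == "dmda", ]
mat <- sapply(mc$cell_id, function(id)
  cell_profile(id, counts[[id]], bins)$corrected)

sw <- denoise_sweep(mat, bins)
write.table(sw$mad_table, "results/denoise_mad.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(sw$mad_table, row.names = FALSE)
best <- sw$mad_table[-1, ][which.min(sw$mad_table$mean_mad[-1]), ]
message(sprintf(
  "mean dMDA MAD %.3f before denoising, best %.3f at the %.0f%% setting",
  sw$mad_table$mean_mad[1], best$mean_mad, 100 * best$fraction))
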