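#!/usr/bin/env Rscript
# Simulate the three-chemistry study cohort: per-cell binned read counts
# with method-specific noise, a ground-truth CNV table per cell, and
# per-cell read-pair records. Writes counts/truth/pairs under results/.

library(scwgacnv)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

# three individuals (two disease, one control), mirroring the study design
cells <- rbind(
  data.frame(cell_id = sprintf("MSA1_P%02d", 1:15), individual_id = "MSA1",
             method = "picoplex"),
  data.frame(cell_id = sprintf("MSA1_T%02d", 1:13), individual_id = "MSA1",
             method = "pta"),
  data.frame(cell_id = sprintf("MSA2_P%02d", 1:12), individual_id = "MSA2",
             method = "picoplex"),
  data.frame(cell_id = sprintf("CTRL_P%02d", 1:7), individual_id = "CTRL",
             method = "picoplex"),
  data.frame(cell_id = sprintf("CTRL_T%02d", 1:12), individual_id = "CTRL",
             method = "pta"),
  data.frame(cell_id = sprintf("MSA1_D%02d", 1:13), individual_id = "MSA1",
             method = "dmda"))

# wider genome and a sparser event menu than the test fixtures: with 59
# cells, somatic events must stay rare enough that two cells do not
# collide within the Mb-scale sharing tolerance by chance
genome <- setNames(rep(100e6, 8), paste0("chr", 1:8))
menu <- data.frame(size_bp = c(5e6, 5e6, 8e6, 3e6),
                   cn = c(1L, 3L, 3L, 1L),
                   frequency = c(0.25, 0.25, 0.15, 0.15))

for (m in unique(cells$method)) {
  mc <- cells[cells$method == m, ]
  bs <- c(picoplex = 250e3, pta = 500e3, dmda = 1e6)[[m]]
  spec <- cohort_spec(mc, genome = genome, cnv_menu = menu, bin_size = bs,
                      mean_reads_per_bin = 200 * bs / 250e3,
                      rng_seed = seed, shared_artifact_seed = seed)
  sim <- simulate_cohort(spec)
  counts <- data.frame(sim$bins[c("chrom", "start", "end")], sim$counts,
                       check.names = FALSE)
  write.table(counts, file.path(out, paste0("counts_", m, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(out, paste0("truth_", m, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(m, ": ", nrow(mc), " cells, ", nrow(sim$bins), " bins of ",
          bs / 1e3, " kb, ", nrow(sim$truth), " planted CNVs")
}

pairs <- simulate_pair_cohort(cells, n_pairs_per_cell = 5000, rng_seed = seed)
pair_tab <- do.call(rbind, lapply(names(pairs), function(id)
  data.frame(cell_id = id, pairs[[id]])))
write.table(pair_tab, file.path(out, "pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cells, file.path(out, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("read pairs: ", nrow(pair_tab), " records across ",
        length(pairs), " cells")
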