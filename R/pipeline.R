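#' Default end-to-end pipeline configuration
#'
#' Bin sizes per chemistry follow the calling resolutions of the analysis:
#' 250 kb for PicoPLEX, 500 kb for PTA; dMDA is routed through PCA
#' denoising at 1 Mb bins or larger, since its read-depth noise precludes
#' direct calling.
#'
#' @param cells cohort manifest (`cell_id`, `individual_id`, `method`).
#' @param seed master seed applied to every stochastic stage.
#' @return nested configuration list.
#' @export
pipeline_config <- function(cells, seed = 1L) {
  list(cells = cells, seed = as.integer(seed),
       genome = synthetic_genome(),
       mean_reads_per_bin = 200,
       bin_size = c(picoplex = 250e3, pta = 500e3, dmda = 1e6),
       denoise = list(enabled = TRUE, fraction = 0.4),
       qc = list(mad_max = 0.3, conf_min = 0.7),
       segment = list(alpha = 0.01, min_width = 5L, n_perm = 10000L),
       call = list(loss_thr = 1.29, gain_thr = 2.80, min_bins = 5L),
       filter = list(share_frac = 0.5,
                     tol_bp = c(picoplex = 2.5e6, pta = 5e6, dmda = 5e6)),
       chimera = list(n_pairs_per_cell = 5000, mq_min = 0))
}

#' Run the full simulated-cohort workflow
#'
#' simulate -> QC -> (denoise for dMDA) -> segment -> call -> filter ->
#' chimera -> report, one pass per chemistry at its bin size, writing each
#' stage's table under `out_dir` plus a JSON run manifest recording every
#' parameter. Deterministic given `config$seed`; stages whose output files
#' already exist are skipped when `resume = TRUE`.
#'
#' @param config from [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @param resume skip stages whose outputs already exist.
#' @return invisibly, a list with `qc`, `calls`, `summary`, `chimera`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out_dir, f)
  if (resume && file.exists(art("summary.tsv"))) {
    message("existing artifacts found; resuming from ", out_dir)
    return(invisible(list(
      qc = utils::read.delim(art("qc.tsv")),
      summary = utils::read.delim(art("summary.tsv")),
      chimera = utils::read.delim(art("chimera.tsv")),
      manifest = jsonlite::read_json(art("run_manifest.json")))))
  }
  cells <- config$cells
  methods <- unique(cells$method)
  if ("dmda" %in% methods && !isTRUE(config$denoise$enabled))
    warning("dMDA read depth is not suitable for direct CNV calling; ",
            "denoising is disabled so dMDA calls will be unreliable")

  qc_all <- list(); calls_all <- list()
  for (m in methods) {
    mc <- cells[cells$method == m, , drop = FALSE]
    bs <- config$bin_size[[m]]
    spec <- cohort_spec(mc, genome = config$genome, bin_size = bs,
                        mean_reads_per_bin = config$mean_reads_per_bin,
                        rng_seed = config$seed,
                        shared_artifact_seed = config$seed)
    sim <- simulate_cohort(spec)
    utils::write.table(sim$truth, art(paste0("truth_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    profiles <- lapply(seq_len(nrow(mc)), function(i)
      cell_profile(mc$cell_id[i], sim$counts[, i], sim$bins,
                   mc$individual_id[i], m))
    mat <- sapply(profiles, function(p) p$corrected)
    colnames(mat) <- mc$cell_id
    if (m == "dmda" && isTRUE(config$denoise$enabled) && nrow(mc) >= 3)
      mat <- pca_denoise(mat, config$denoise$fraction)

    res <- lapply(seq_along(profiles), function(i) {
      call_cell(profiles[[i]], values = mat[, i],
                alpha = config$segment$alpha,
                min_width = config$segment$min_width,
                n_perm = config$segment$n_perm,
                rng_seed = derive_seed(config$seed, mc$cell_id[i]),
                loss_thr = config$call$loss_thr,
                gain_thr = config$call$gain_thr,
                min_bins = config$call$min_bins)
    })
    qc <- do.call(rbind, lapply(seq_along(profiles), function(i)
      qc_report(profiles[[i]], res[[i]]$segments,
                config$qc$mad_max, config$qc$conf_min)))
    calls <- do.call(rbind, lapply(res, `[[`, "calls"))
    calls <- calls[calls$cell_id %in% qc$cell_id[qc$passes], , drop = FALSE]
    qc_all[[m]] <- qc; calls_all[[m]] <- calls
  }
  qc <- do.call(rbind, qc_all); rownames(qc) <- NULL
  calls <- do.call(rbind, calls_all); rownames(calls) <- NULL

  calls <- match_shared(calls, tol_bp = config$filter$tol_bp)
  n_passed <- table(merge(qc[qc$passes, ], cells)$individual_id)
  retained <- filter_artifacts(calls, as.list(n_passed),
                               config$filter$share_frac)
  retained <- annotate_subtelomeric(retained, config$genome)

  pair_sets <- simulate_pair_cohort(
    cells, config$chimera$n_pairs_per_cell, rng_seed = config$seed)
  chim <- do.call(rbind, lapply(names(pair_sets), function(id) {
    fr <- summarize_chimeras(pair_sets[[id]], config$chimera$mq_min)$fractions
    data.frame(cell_id = id, t(fr))
  }))

  summary <- summarize_cohort(qc, retained, cells)

  utils::write.table(qc, art("qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_calls_bed(retained, art("calls.bed"))
  utils::write.table(chim, art("chimera.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary, art("summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(seed = config$seed, parameters = config[-1],
                   n_cells = nrow(cells),
                   outputs = c("qc.tsv", "calls.bed", "chimera.tsv",
                               "summary.tsv"))
  jsonlite::write_json(manifest, art("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(qc = qc, calls = retained, summary = summary,
                 chimera = chim, manifest = manifest))
}

#' Write CNV calls as BED6+
#'
#' Columns: chrom, start, end, cell_id, cn_int, type, n_bins, cn_est.
#'
#' @param calls call table.
#' @param path output file.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$chrom, start = format(calls$start, scientific = FALSE, trim = TRUE),
                    end = format(calls$end, scientific = FALSE, trim = TRUE),
                    name = calls$cell_id, score = calls$cn_int,
                    strand = calls$type, n_bins = calls$n_bins,
                    cn_est = round(calls$cn_est, 4))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
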