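#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value under the convention that all
#' tables with probability at most that of the observed table (within a
#' small tolerance factor) contribute — the `fisher.test` convention. A
#' zero margin returns p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L),
            all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin; p = 1 by convention")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact when the samples are tie-free and n1*n2 <= 400 (full enumeration
#' of the U distribution); otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param a,b numeric samples (e.g. CNV sizes per method).
#' @return two-sided p-value.
#' @export
rank_sum <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L || length(a) + length(b) < 2L)
    stop("need at least two observations")
  exact <- length(a) * length(b) <= 400 && !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Cohort roll-up arithmetic from integer counts
#'
#' The headline cohort fractions, always recomputed from integer counts:
#' percentage of QC-passed cells carrying at least one CNV, percentage of
#' calls that are gains, and mean calls per CNV-bearing cell.
#'
#' @param n_passed QC-passed cells.
#' @param n_cnv_cells passed cells with at least one retained call.
#' @param n_calls total retained calls.
#' @param n_gains gain calls among them.
#' @return list `cnv_cell_pct`, `gain_pct`, `mean_calls_per_cnv_cell`,
#'   `total_calls`.
#' @export
cohort_rollup <- function(n_passed, n_cnv_cells, n_calls, n_gains) {
  stopifnot(n_cnv_cells <= n_passed, n_gains <= n_calls)
  list(cnv_cell_pct = 100 * n_cnv_cells / n_passed,
       gain_pct = if (n_calls > 0) 100 * n_gains / n_calls else 0,
       mean_calls_per_cnv_cell =
         if (n_cnv_cells > 0) n_calls / n_cnv_cells else 0,
       total_calls = n_calls)
}

#' Cohort summary table
#'
#' Per individual x method: cells, QC pass rate, fraction of passed cells
#' with at least one retained CNV, and total/gain/loss call counts; the
#' cohort roll-up is attached as attribute `rollup`.
#'
#' @param qc per-cell QC table (`cell_id`, `passes`).
#' @param calls retained call table (`cell_id`, `type`).
#' @param manifest cell manifest (`cell_id`, `individual_id`, `method`).
#' @return data.frame, one row per individual x method.
#' @export
summarize_cohort <- function(qc, calls, manifest) {
  stopifnot(all(qc$cell_id %in% manifest$cell_id))
  qc <- merge(qc, manifest, by = "cell_id")
  rows <- list()
  for (ind in unique(manifest$individual_id)) {
    for (m in unique(manifest$method[manifest$individual_id == ind])) {
      grp <- qc[qc$individual_id == ind & qc$method == m, ]
      passed <- grp$cell_id[grp$passes]
      cc <- calls[calls$cell_id %in% passed, , drop = FALSE]
      n_cnv_cells <- length(unique(cc$cell_id))
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = ind, method = m,
        n_cells = nrow(grp), n_passed = length(passed),
        pass_pct = if (nrow(grp)) 100 * length(passed) / nrow(grp) else NA,
        n_cnv_cells = n_cnv_cells,
        cnv_cell_pct = if (length(passed))
          100 * n_cnv_cells / length(passed) else NA,
        total_calls = nrow(cc),
        gains = sum(cc$type == "gain"),
        losses = sum(cc$type == "loss"))
    }
  }
  out <- do.call(rbind, rows)
  passed_all <- qc$cell_id[qc$passes]
  cc <- calls[calls$cell_id %in% passed_all, , drop = FALSE]
  attr(out, "rollup") <- cohort_rollup(
    length(passed_all), length(unique(cc$cell_id)),
    nrow(cc), sum(cc$type == "gain"))
  out
}

#' Match calls against a ground-truth table
#'
#' A truth event is recovered when some call in the same cell, on the same
#' chromosome and of the same type overlaps at least `min_overlap_frac` of
#' the truth span; a call is correct when its overlap with some such truth
#' event covers at least `min_overlap_frac` of the call span.
#'
#' @param calls call table (`cell_id`, `chrom`, `start`, `end`, `type`).
#' @param truth truth table (`cell_id`, `chrom`, `start`, `end`, `cn`).
#' @param min_overlap_frac matching stringency (default 0.5).
#' @return list `recall`, `precision`, `n_truth`, `n_calls`.
#' @export
evaluate_recovery <- function(calls, truth, min_overlap_frac = 0.5) {
  truth$type <- ifelse(truth$cn < 2, "loss", "gain")
  ov <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))
  truth_hit <- vapply(seq_len(nrow(truth)), function(i) {
    cc <- calls[calls$cell_id == truth$cell_id[i] &
                  calls$chrom == truth$chrom[i] &
                  calls$type == truth$type[i], , drop = FALSE]
    if (!nrow(cc)) return(FALSE)
    any(ov(cc$start, cc$end, truth$start[i], truth$end[i]) >=
          min_overlap_frac * (truth$end[i] - truth$start[i]))
  }, logical(1))
  call_hit <- vapply(seq_len(nrow(calls)), function(i) {
    tt <- truth[truth$cell_id == calls$cell_id[i] &
                  truth$chrom == calls$chrom[i] &
                  truth$type == calls$type[i], , drop = FALSE]
    if (!nrow(tt)) return(FALSE)
    any(ov(tt$start, tt$end, calls$start[i], calls$end[i]) >=
          min_overlap_frac * (calls$end[i] - calls$start[i]))
  }, logical(1))
  list(recall = if (nrow(truth)) mean(truth_hit) else NA_real_,
       precision = if (nrow(calls)) mean(call_hit) else NA_real_,
       n_truth = nrow(truth), n_calls = nrow(calls))
}
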