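#' Group CNV calls shared across cells
#'
#' Two calls of the same chromosome and type are linked when both their
#' start and end positions lie within a method-dependent tolerance (2.5 Mb
#' for PicoPLEX cells, 5 Mb for PTA); groups are the transitive closure of
#' these links, and mixed-method pairs use the larger tolerance of the
#' two. Recurrent groups point to germline variants or dry/wet-lab
#' artifacts rather than somatic events.
#'
#' @param calls call table from [extract_cnvs()] (needs `chrom`, `start`,
#'   `end`, `type`, `cell_id`, `method`).
#' @param tol_bp named tolerances per method (bp).
#' @param default_tol tolerance for methods not listed.
#' @return `calls` with an integer `group` column.
#' @export
match_shared <- function(calls,
                         tol_bp = c(picoplex = 2.5e6, pta = 5e6),
                         default_tol = 2.5e6) {
  n <- nrow(calls)
  if (n == 0L) { calls$group <- integer(0); return(calls) }
  tol_of <- function(m) {
    t <- tol_bp[m]
    ifelse(is.na(t), default_tol, t)
  }
  tol <- unname(tol_of(as.character(calls$method)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (calls$chrom[i] != calls$chrom[j] ||
          calls$type[i] != calls$type[j]) next
      t <- max(tol[i], tol[j])
      if (abs(calls$start[i] - calls$start[j]) <= t &&
          abs(calls$end[i] - calls$end[j]) <= t) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  calls$group <- match(roots, unique(roots))
  calls
}

#' Remove multi-cell artifact calls
#'
#' Drops every call belonging to a group that (a) spans at least half of
#' the QC-passed cells of its individual, or (b) spans two or more
#' individuals. The retained set is order-independent.
#'
#' @param calls grouped calls from [match_shared()] (needs `group`,
#'   `cell_id`, `individual_id`).
#' @param n_cells_per_individual named vector: QC-passed cell count per
#'   individual.
#' @param share_frac fraction of an individual's cells above which a group
#'   is deemed artifactual (default 0.5, inclusive).
#' @return retained calls (group column kept).
#' @export
filter_artifacts <- function(calls, n_cells_per_individual,
                             share_frac = 0.5) {
  if (nrow(calls) == 0L) return(calls)
  drop <- logical(nrow(calls))
  for (g in unique(calls$group)) {
    idx <- which(calls$group == g)
    inds <- unique(calls$individual_id[idx])
    if (length(inds) >= 2L) { drop[idx] <- TRUE; next }
    n_cells <- length(unique(calls$cell_id[idx]))
    n_total <- n_cells_per_individual[[inds]]
    if (!is.null(n_total) && n_cells >= share_frac * n_total)
      drop[idx] <- TRUE
  }
  calls[!drop, , drop = FALSE]
}

#' Flag sub-telomeric calls
#'
#' A call is sub-telomeric when it starts within `window_bp` of the
#' p-terminus or ends within `window_bp` of the q-terminus of its
#' chromosome. The default window is two bin widths.
#'
#' @param calls call table.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param window_bp window size (bp).
#' @return `calls` with logical `subtelomeric` column.
#' @export
annotate_subtelomeric <- function(calls, chrom_lengths, window_bp = 500e3) {
  stopifnot(window_bp > 0)
  len <- chrom_lengths[as.character(calls$chrom)]
  calls$subtelomeric <- calls$start < window_bp |
    calls$end > len - window_bp
  calls
}

#' Select calls lying mostly in novel reference regions
#'
#' Keeps calls whose overlap with the union of "novel" intervals (sequence
#' present only in the newer reference assembly) covers at least
#' `min_overlap_frac` of the call span — the criterion used to isolate
#' gains specific to a complete reference.
#'
#' @param calls call table.
#' @param novel_bed data.frame `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param min_overlap_frac minimum covered fraction of the call (default
#'   0.5).
#' @return the qualifying subset of `calls`, with `novel_frac` column.
#' @export
novel_region_gains <- function(calls, novel_bed, min_overlap_frac = 0.5) {
  if (!is.data.frame(novel_bed) ||
      !all(c("chrom", "start", "end") %in% names(novel_bed)) ||
      (nrow(novel_bed) > 0 && any(novel_bed$end <= novel_bed$start)))
    stop("malformed novel-region BED")
  if (nrow(calls) == 0L) { calls$novel_frac <- numeric(0); return(calls) }
  novel <- GenomicRanges::reduce(GenomicRanges::GRanges(
    novel_bed$chrom,
    IRanges::IRanges(novel_bed$start + 1, novel_bed$end)))
  gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$start + 1, calls$end))
  hits <- GenomicRanges::findOverlaps(gr, novel)
  piece <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                     novel[S4Vectors::subjectHits(hits)])
  covered <- numeric(length(gr))
  if (length(hits)) {
    w <- tapply(IRanges::width(piece), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(w))] <- as.numeric(w)
  }
  calls$novel_frac <- covered / (calls$end - calls$start)
  calls[calls$novel_frac >= min_overlap_frac, , drop = FALSE]
}

#' Detect whole-chromosome aneusomies
#'
#' When calls of one type in one cell cover at least `min_cover` of a
#' chromosome (allowing small spared gaps, as when two large losses add up
#' to the whole chromosome), they are replaced by a single
#' whole-chromosome event.
#'
#' @param calls one cell's call table.
#' @param chrom_lengths named chromosome lengths.
#' @param min_cover covered fraction declaring aneusomy (default 0.95).
#' @return list with `aneusomies` (data.frame `chrom`, `type`, `cell_id`,
#'   `covered_frac`) and `calls` (input with chromosome-wide groups
#'   replaced by full-chromosome calls).
#' @export
aneusomy_check <- function(calls, chrom_lengths, min_cover = 0.95) {
  an <- data.frame(chrom = character(), type = character(),
                   cell_id = character(), covered_frac = numeric())
  if (nrow(calls) == 0L) return(list(aneusomies = an, calls = calls))
  keep <- rep(TRUE, nrow(calls))
  extra <- list()
  for (cell in unique(calls$cell_id)) {
    for (ch in unique(calls$chrom[calls$cell_id == cell])) {
      for (ty in c("gain", "loss")) {
        idx <- which(calls$cell_id == cell & calls$chrom == ch &
                       calls$type == ty)
        if (!length(idx)) next
        ir <- IRanges::reduce(IRanges::IRanges(calls$start[idx] + 1,
                                               calls$end[idx]))
        frac <- sum(IRanges::width(ir)) / chrom_lengths[[ch]]
        if (frac >= min_cover) {
          keep[idx] <- FALSE
          an <- rbind(an, data.frame(chrom = ch, type = ty,
                                     cell_id = cell, covered_frac = frac))
          whole <- calls[idx[1], , drop = FALSE]
          whole$start <- 0
          whole$end <- chrom_lengths[[ch]]
          whole$n_bins <- sum(calls$n_bins[idx])
          extra[[length(extra) + 1L]] <- whole
        }
      }
    }
  }
  out <- rbind(calls[keep, , drop = FALSE], do.call(rbind, extra))
  rownames(out) <- NULL
  list(aneusomies = an, calls = out)
}
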