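#' Count aligned fragments into bins
#'
#' Assigns each fragment to the unique bin containing its leftmost mapped
#' position, after discarding fragments below a mapping-quality cutoff.
#' Fragments on chromosomes absent from the scheme, or beyond the recorded
#' chromosome end, are skipped and tallied rather than counted.
#'
#' @param fragments data.frame with columns `chrom`, `pos` (0-based leftmost
#'   mapped position) and optionally `mq` (mapping quality; absent means
#'   all retained).
#' @param bins a [build_bins()] scheme.
#' @param mq_min minimum mapping quality; fragments with `mq < mq_min` are
#'   excluded. The study's stratified re-calling uses cutoffs 0, 1 and 10.
#' @return list with `counts` (integer vector, one per bin) and `skipped`
#'   (fragments outside the scheme).
#' @export
count_fragments <- function(fragments, bins, mq_min = 0) {
  stopifnot(is.data.frame(fragments), all(c("chrom", "pos") %in% names(fragments)),
            mq_min >= 0)
  if (!is.null(fragments$mq)) {
    fragments <- fragments[fragments$mq >= mq_min, , drop = FALSE]
  }
  counts <- integer(nrow(bins))
  skipped <- 0L
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    pos <- fragments$pos[fragments$chrom == ch]
    if (length(pos) == 0L) next
    chrom_end <- bins$end[idx[length(idx)]]
    bad <- pos < 0 | pos >= chrom_end
    skipped <- skipped + sum(bad)
    pos <- pos[!bad]
    if (length(pos) == 0L) next
    j <- findInterval(pos, bins$start[idx])  # half-open bins, pos >= start
    tab <- tabulate(j, nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  skipped <- skipped + sum(!fragments$chrom %in% bins$chrom)
  list(counts = counts, skipped = skipped)
}

#' Normalise raw bin counts to depth ratios
#'
#' Each bin's count is divided by the cell's mean raw count over autosomal
#' bins, so a diploid cell centres at ratio 1 and the autosomal mean is
#' exactly 1. Sex-chromosome bins are scaled by the same factor but do not
#' contribute to it.
#'
#' @param raw numeric vector of raw counts, one per bin.
#' @param bins matching `bin_scheme`.
#' @return numeric vector of normalised ratios.
#' @export
normalize_counts <- function(raw, bins) {
  stopifnot(length(raw) == nrow(bins), all(raw >= 0))
  auto <- is_autosome(bins)
  m <- mean(raw[auto])
  if (!is.finite(m) || m <= 0)
    stop("cell has zero mean autosomal depth; unusable")
  raw / m
}

#' GC-correct normalised depth ratios
#'
#' Fits a locally weighted regression (LOWESS) of normalised depth on bin GC
#' fraction and divides each bin by the fitted trend, then rescales so the
#' autosomal mean is 1 again. With fewer than 10 distinct GC values the
#' correction is skipped and the input returned unchanged.
#'
#' The trend is fitted on autosomal bins only (sex chromosomes sit at a
#' different copy-number level and would bend it) and applied to all bins.
#' The span is widened automatically when the scheme holds few bins, so
#' the local fits always see a stable number of points.
#'
#' @param normalized normalised ratios from [normalize_counts()].
#' @param bins `bin_scheme` with per-bin `gc`.
#' @param smoother_fraction LOWESS span (fraction of points in each local
#'   fit); default 0.05 with 3 robustness iterations, floored so that a
#'   local fit uses at least 20 bins.
#' @return corrected ratios, autosomal mean 1.
#' @export
gc_correct <- function(normalized, bins, smoother_fraction = 0.05) {
  gc <- bins$gc
  stopifnot(length(normalized) == nrow(bins))
  if (anyNA(gc)) stop("gc must be known for all bins")
  if (length(unique(gc)) < 10L) {
    warning("fewer than 10 distinct GC values; correction skipped")
    return(normalized)
  }
  auto <- is_autosome(bins)
  f_used <- max(smoother_fraction, min(1, 20 / sum(auto)))
  fit <- stats::lowess(gc[auto], normalized[auto], f = f_used, iter = 3)
  trend <- stats::approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y
  trend[trend <= 0.05] <- 0.05  # guard against pathological local fits
  corrected <- normalized / trend
  corrected / mean(corrected[auto])
}

#' Assemble a per-cell depth profile
#'
#' Bundles raw, normalised and GC-corrected depth for one cell.
#'
#' @param cell_id,individual_id,method cell labels (method is the WGA
#'   chemistry: picoplex, pta or dmda).
#' @param raw raw bin counts.
#' @param bins `bin_scheme`.
#' @param gc_smoother_fraction passed to [gc_correct()].
#' @return list of class `cell_profile`.
#' @export
cell_profile <- function(cell_id, raw, bins, individual_id = NA_character_,
                         method = NA_character_, gc_smoother_fraction = 0.05) {
  normalized <- normalize_counts(raw, bins)
  corrected <- if (all(is.na(bins$gc))) normalized
  else gc_correct(normalized, bins, gc_smoother_fraction)
  structure(list(cell_id = cell_id, individual_id = individual_id,
                 method = method, raw = raw, normalized = normalized,
                 corrected = corrected, bins = bins),
            class = "cell_profile")
}
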