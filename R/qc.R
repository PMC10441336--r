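#' Neighbour-difference MAD: per-cell amplification evenness
#'
#' The scaled median absolute deviation of differences between neighbouring
#' autosomal bins of a normalised depth profile. Being median-based it is
#' robust to genuine copy-number steps, so it measures amplification noise
#' rather than biology. Differences are taken within chromosomes only;
#' chromosome-boundary pairs are excluded.
#'
#' @param x normalised (or GC-corrected) depth ratios.
#' @param bins matching `bin_scheme`; only autosomal bins are used.
#' @param constant consistency constant applied to the median absolute
#'   deviation; the R default 1.4826 makes it estimate the standard
#'   deviation under normality.
#' @return non-negative scalar.
#' @export
compute_mad <- function(x, bins, constant = 1.4826) {
  stopifnot(length(x) == nrow(bins))
  auto <- is_autosome(bins)
  x <- x[auto]
  ch <- bins$chrom[auto]
  if (length(x) < 3L) stop("need at least 3 autosomal bins")
  d <- unlist(lapply(split(x, factor(ch, unique(ch))), diff), use.names = FALSE)
  if (length(d) == 0L) stop("no within-chromosome neighbour pairs")
  stats::mad(d, constant = constant)
}

#' Lorenz curve and Gini coefficient of coverage uniformity
#'
#' Sorts bins by depth and accumulates: the curve plots the cumulative
#' fraction of reads against the cumulative fraction of the genome. Perfect
#' uniformity gives the diagonal (Gini 0); concentration of reads in few
#' bins bows the curve away from it.
#'
#' @param x non-negative depth values (one per bin).
#' @return list with `genome_frac`, `read_frac` (each starting at 0) and
#'   `gini` = 1 - 2 x area under the curve.
#' @export
lorenz_curve <- function(x) {
  stopifnot(all(x >= 0))
  if (sum(x) == 0) stop("all-zero profile has no Lorenz curve")
  x <- sort(x)
  n <- length(x)
  gf <- c(0, seq_len(n) / n)
  rf <- c(0, cumsum(x) / sum(x))
  auc <- sum((rf[-1] + rf[-length(rf)]) / 2 * diff(gf))
  list(genome_frac = gf, read_frac = rf, gini = 1 - 2 * auc)
}

#' Integer-copy-number confidence score
#'
#' Measures how close a cell's segment copy-number estimates sit to whole
#' integers: intermediate states indicate uneven amplification. Each
#' autosomal segment scores `max(0, 1 - 2|cn_est - round(cn_est)|)` and
#' scores are averaged weighted by segment length in bins, giving a value
#' in [0, 1] (1 = perfectly integer).
#'
#' @param segments segment table with columns `chrom`, `n_bins`, `cn_est`
#'   (as produced by [assign_copy_number()]).
#' @return scalar in [0, 1].
#' @export
confidence_score <- function(segments) {
  if (is.list(segments) && !is.data.frame(segments) &&
      !is.null(segments$segments)) segments <- segments$segments
  if (is.null(segments) || nrow(segments) == 0L)
    stop("empty segmentation")
  seg <- segments[is_autosome(segments$chrom), , drop = FALSE]
  if (nrow(seg) == 0L) stop("no autosomal segments")
  sc <- pmax(0, 1 - 2 * abs(seg$cn_est - round(seg$cn_est)))
  sum(sc * seg$n_bins) / sum(seg$n_bins)
}

#' QC gate for copy-number calling
#'
#' A cell enters CNV calling only if its MAD is at most `mad_max` and its
#' confidence score at least `conf_min`; both boundary values pass.
#'
#' @param mad,confidence per-cell metrics.
#' @param mad_max MAD cutoff (cells with MAD > 0.3 are discarded by default).
#' @param conf_min minimum confidence (default 0.7).
#' @return logical.
#' @export
qc_gate <- function(mad, confidence, mad_max = 0.3, conf_min = 0.7) {
  mad <= mad_max & confidence >= conf_min
}

#' Per-cell QC report
#'
#' @param profile a [cell_profile()].
#' @param segments the cell's copy-number segmentation (for the confidence
#'   score); `NULL` yields `NA` confidence and the gate uses MAD only.
#' @param mad_max,conf_min gate parameters, see [qc_gate()].
#' @return one-row data.frame: `cell_id`, `mad`, `gini`, `confidence`,
#'   `passes`.
#' @export
qc_report <- function(profile, segments = NULL, mad_max = 0.3, conf_min = 0.7) {
  mad <- compute_mad(profile$corrected, profile$bins)
  gini <- lorenz_curve(profile$corrected[is_autosome(profile$bins)])$gini
  conf <- if (is.null(segments)) NA_real_ else confidence_score(segments)
  passes <- if (is.na(conf)) mad <= mad_max
  else qc_gate(mad, conf, mad_max, conf_min)
  data.frame(cell_id = profile$cell_id, mad = mad, gini = gini,
             confidence = conf, passes = passes)
}
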