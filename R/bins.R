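#' Genomic bin schemes
#'
#' A bin scheme is the ordered set of genomic intervals into which aligned
#' fragments are counted for read-depth copy-number analysis. Bins are
#' 0-based half-open (BED convention) and carry per-bin GC content and
#' mappability where known.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp,
#'   in the desired chromosome order.
#' @param mode `"fixed"` for constant-width bins, `"variable"` for bins of
#'   equal cumulative mappability mass.
#' @param size_bp nominal bin size in bp. In variable mode each bin holds
#'   `size_bp` of cumulative mappability, so regions of poor mappability
#'   produce wider bins.
#' @param mappability_track data.frame with columns `chrom`, `start`, `end`,
#'   `mappability` (step function over each chromosome; 0-based half-open).
#'   Required in variable mode.
#' @return A data.frame of class `bin_scheme` with columns `chrom`, `start`,
#'   `end`, `gc`, `mappability` and attribute `bin_size_label`.
#' @examples
#' build_bins(c(chr1 = 1e6), size_bp = 250e3)
#' @export
build_bins <- function(chrom_lengths, mode = c("fixed", "variable"),
                       size_bp, mappability_track = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) > 0,
            !is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  if (!is.numeric(size_bp) || length(size_bp) != 1L || size_bp <= 0)
    stop("size_bp must be a single positive number")
  if (mode == "variable" && is.null(mappability_track))
    stop("variable mode requires a mappability track")

  pieces <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len < size_bp) {
      warning("chromosome ", ch, " shorter than one bin; kept whole")
      return(data.frame(chrom = ch, start = 0, end = len))
    }
    if (mode == "fixed") {
      starts <- seq(0, len - 1, by = size_bp)
      ends <- pmin(starts + size_bp, len)
      return(data.frame(chrom = ch, start = starts, end = ends))
    }
    trk <- mappability_track[mappability_track$chrom == ch, , drop = FALSE]
    if (nrow(trk) == 0L)
      stop("no mappability for chromosome ", ch)
    trk <- trk[order(trk$start), , drop = FALSE]
    cuts_at_mass(ch, len, trk, size_bp)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$gc <- NA_real_
  out$mappability <- if (mode == "variable")
    track_mean(out, mappability_track) else 1
  attr(out, "bin_size_label") <- format_bp(size_bp)
  class(out) <- c("bin_scheme", "data.frame")
  out
}

# Cut one chromosome into bins of equal cumulative mappability mass.
cuts_at_mass <- function(ch, len, trk, mass_per_bin) {
  seg_start <- trk$start
  seg_end <- pmin(trk$end, len)
  w <- trk$mappability
  seg_mass <- (seg_end - seg_start) * w
  cum <- cumsum(seg_mass)
  total <- cum[length(cum)]
  n_bins <- max(1L, floor(total / mass_per_bin))
  # spread the sub-bin remainder evenly instead of dumping it on the
  # terminal bin
  targets <- (total / n_bins) * seq_len(n_bins - 1L)
  # invert the cumulative-mass step function at each target
  starts <- 0
  for (tg in targets) {
    i <- which(cum >= tg)[1]
    prev <- if (i == 1L) 0 else cum[i - 1L]
    pos <- seg_start[i] + (tg - prev) / w[i]
    starts <- c(starts, pos)
  }
  starts <- floor(starts)
  data.frame(chrom = ch, start = starts, end = c(starts[-1], len))
}

# Length-weighted mean of a step-function track over each bin.
track_mean <- function(bins, track) {
  vapply(seq_len(nrow(bins)), function(i) {
    ch <- bins$chrom[i]; s <- bins$start[i]; e <- bins$end[i]
    trk <- track[track$chrom == ch, , drop = FALSE]
    ov_s <- pmax(trk$start, s); ov_e <- pmin(trk$end, e)
    w <- pmax(0, ov_e - ov_s)
    if (sum(w) == 0) return(0)
    sum(w * trk$mappability) / sum(w)
  }, numeric(1))
}

format_bp <- function(bp) {
  if (bp %% 1e6 == 0) paste0(bp / 1e6, " Mb")
  else if (bp %% 1e3 == 0) paste0(bp / 1e3, " kb")
  else paste0(bp, " bp")
}

#' Autosome indicator for bins or chromosome labels
#'
#' Sex chromosomes are kept in bin schemes but excluded from normalisation
#' means and evenness statistics, which are computed across the autosomes.
#'
#' @param x a `bin_scheme` or a character vector of chromosome labels.
#' @return logical vector.
#' @export
is_autosome <- function(x) {
  ch <- if (is.data.frame(x)) x$chrom else x
  !(sub("^chr", "", ch) %in% c("X", "Y", "M", "MT"))
}
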