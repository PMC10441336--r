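#' Circular binary segmentation of a depth-ratio profile
#'
#' Recursive change-point detection on binned depth ratios, per chromosome,
#' using the max-t binary split with a permutation reference distribution:
#' at each stage the candidate split maximising the two-sample t statistic
#' is accepted only if its permutation p-value falls below `alpha` and both
#' arms hold at least `min_width` bins. Splitting recurses into accepted
#' arms; adjacent segments whose means differ by less than `merge_delta`
#' are merged afterwards (an undo-splits surrogate). The permutation loop
#' stops early once significance is no longer attainable.
#'
#' @param values corrected (or denoised) depth ratios, one per bin.
#' @param bins matching `bin_scheme`.
#' @param alpha permutation significance level for accepting a split
#'   (default 0.01).
#' @param min_width minimum bins per segment arm (default 5).
#' @param n_perm permutations per candidate split (default 10000).
#' @param rng_seed seed making the permutation reference reproducible.
#' @param merge_delta post-hoc merge threshold on adjacent segment means.
#' @return list of class `segment_set`: `segments` data.frame (`chrom`,
#'   `start_bin`, `end_bin` 1-based inclusive within chromosome, `start`,
#'   `end` bp, `n_bins`, `mean_ratio`), plus `ploidy` (NA until fitted).
#' @export
cbs_segment <- function(values, bins, alpha = 0.01, min_width = 5L,
                        n_perm = 10000L, rng_seed = 1L, merge_delta = 0.05) {
  stopifnot(length(values) == nrow(bins), alpha > 0, alpha < 1,
            min_width >= 2L)
  segs <- with_seed(as.integer(rng_seed), function() {
    out <- list()
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      x <- values[idx]
      bounds <- segment_vector(x, alpha, min_width, n_perm)
      bounds <- merge_segments(x, bounds, merge_delta)
      for (b in bounds) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start_bin = b[1], end_bin = b[2],
          start = bins$start[idx[b[1]]], end = bins$end[idx[b[2]]],
          n_bins = b[2] - b[1] + 1L,
          mean_ratio = mean(x[b[1]:b[2]]))
      }
    }
    do.call(rbind, out)
  })
  rownames(segs) <- NULL
  structure(list(segments = segs, ploidy = NA_real_), class = "segment_set")
}

# Recursive max-t arc splitting of one chromosome; returns list of
# c(lo, hi) 1-based inclusive boundaries in genomic order.
segment_vector <- function(x, alpha, min_width, n_perm) {
  n <- length(x)
  if (n < 2L * min_width) return(list(c(1L, n)))
  stack <- list(c(1L, n))
  done <- list()
  while (length(stack)) {
    rg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sp <- best_split(x[rg[1]:rg[2]], min_width, alpha, n_perm)
    if (is.null(sp)) {
      done[[length(done) + 1L]] <- rg
      next
    }
    # arc (i, j] -> cutpoints after bins i and j (relative); 0 or n means
    # the arc touches that end and contributes no cut there
    cuts <- rg[1] - 1L + setdiff(c(sp$i, sp$j), c(0L, rg[2] - rg[1] + 1L))
    lo <- c(rg[1], cuts + 1L)
    hi <- c(cuts, rg[2])
    for (p in rev(seq_along(lo)))
      stack[[length(stack) + 1L]] <- c(lo[p], hi[p])
  }
  done[order(vapply(done, `[`, integer(1), 1L))]
}

#' Best circular-segmentation arc of a vector
#'
#' The arc (i, j] (0-based boundaries) maximising the two-sample t
#' statistic between the arc and its complement, subject to every
#' resulting segment holding at least `min_width` bins. Exposed mainly so
#' the search can be validated against brute-force enumeration.
#'
#' @param x numeric vector.
#' @param min_width minimum segment width.
#' @return list with `stat` (the scale-free statistic
#'   `|mean_arc - mean_rest| * sqrt(m(n-m))`), `i` and `j`; `stat < 0`
#'   when no arc satisfies the constraints.
#' @export
cbs_best_arc <- function(x, min_width = 5L) {
  .arc_max(as.numeric(x), as.integer(min_width))
}

# Max-t arc with sequential permutation test; NULL if not accepted.
best_split <- function(x, min_width, alpha, n_perm) {
  n <- length(x)
  if (n < 2L * min_width) return(NULL)
  arc <- .arc_max(x, min_width)
  if (!is.finite(arc$stat) || arc$stat <= 0) return(NULL)
  exceed <- .arc_perm_exceed(x, min_width, arc$stat, as.integer(n_perm),
                             alpha)
  if (exceed == -2L) return(arc)       # curtailed early acceptance
  if (exceed < 0L) return(NULL)        # curtailed rejection
  p <- (exceed + 1) / (n_perm + 1)
  if (p < alpha) arc else NULL
}

# Merge adjacent boundaries whose segment means differ by < delta.
merge_segments <- function(x, bounds, delta) {
  if (length(bounds) < 2L) return(bounds)
  out <- list(bounds[[1]])
  for (b in bounds[-1]) {
    last <- out[[length(out)]]
    m1 <- mean(x[last[1]:last[2]])
    m2 <- mean(x[b[1]:b[2]])
    if (abs(m1 - m2) < delta) {
      out[[length(out)]] <- c(last[1], b[2])
    } else {
      out[[length(out) + 1L]] <- b
    }
  }
  out
}

#' Fit a cell's average ploidy
#'
#' Grid search for the multiplier mapping segment depth ratios to
#' near-integer copy numbers: minimises the bin-weighted sum of squared
#' distances of `mean_ratio * p` from the nearest integer over autosomal
#' segments. Among candidates whose objective lies within 30% of the
#' minimum the smallest ploidy wins (exact ties included), so degeneracy-level
#' differences never override ploidy parsimony.
#'
#' Only autosomal segments of at least `min_fit_bins` bins enter the fit:
#' a short noisy segment at a fractional ratio can otherwise be matched
#' exactly by an inflated ploidy (the free-scale degeneracy), dragging the
#' whole cell to tetraploid.
#'
#' @param segset a `segment_set` (or its `segments` data.frame).
#' @param grid candidate ploidies (default 1.5 to 5.5 by 0.05).
#' @param min_fit_bins minimum segment size entering the fit (default 10;
#'   all segments are used when none qualify).
#' @return fitted ploidy (scalar).
#' @export
fit_ploidy <- function(segset, grid = seq(1.5, 5.5, by = 0.05),
                       min_fit_bins = 10L) {
  seg <- if (is.data.frame(segset)) segset else segset$segments
  if (is.null(seg) || nrow(seg) == 0L) stop("no segments")
  if (length(grid) == 0L) stop("empty ploidy grid")
  seg <- seg[is_autosome(seg$chrom), , drop = FALSE]
  if (nrow(seg) == 0L) stop("no autosomal segments")
  if (any(seg$n_bins >= min_fit_bins))
    seg <- seg[seg$n_bins >= min_fit_bins, , drop = FALSE]
  obj <- vapply(grid, function(p) {
    cn <- seg$mean_ratio * p
    sum(seg$n_bins * (cn - round(cn))^2)
  }, numeric(1))
  # parsimony: a genuinely wrong ploidy misfits by orders of magnitude
  # (integer mismatch on most bins), while the free-scale degeneracy
  # undercuts the true ploidy by tens of percent at most — prefer the
  # smallest candidate within 30% of the minimal objective
  grid[which(obj <= min(obj) * 1.3 + 1e-12)[1]]
}

#' Assign copy-number estimates to segments
#'
#' @param segset `segment_set` from [cbs_segment()].
#' @param ploidy fitted cell ploidy from [fit_ploidy()].
#' @return the `segment_set` with `cn_est = mean_ratio * ploidy`,
#'   `cn_int = round(cn_est)` and `ploidy` recorded.
#' @export
assign_copy_number <- function(segset, ploidy) {
  seg <- segset$segments
  seg$cn_est <- seg$mean_ratio * ploidy
  seg$cn_int <- as.integer(round(seg$cn_est))
  segset$segments <- seg
  segset$ploidy <- ploidy
  segset
}

#' Derive gain/loss copy-number thresholds from the cohort
#'
#' Pools per-segment copy-number estimates from QC-passed cells (segments
#' of `min_bins` to `max_bins` bins; the upper cap is the size of the
#' smallest chromosome in the study's human binning, 127 bins) and places
#' each threshold in the gap between the diploid mode and the flanking
#' CN-1 / CN-3 mode: the midpoint between the outer 99.5th/0.5th
#' percentile of the flanking mode and the facing 0.5th/99.5th percentile
#' of the diploid mode. A missing flanking mode anchors at CN 1 or 3. With
#' `derive = FALSE`, or fewer than 20 eligible segments, the configured
#' defaults (1.29 loss, 2.80 gain) are returned.
#'
#' @param segments pooled segment data.frame with `n_bins` and `cn_est`
#'   (e.g. rbind of QC-passed cells' `segment_set$segments`).
#' @param min_bins,max_bins segment-size eligibility window (5 and 127).
#' @param derive set `FALSE` to return `defaults` unconditionally.
#' @param defaults named vector `c(loss = 1.29, gain = 2.80)`.
#' @return named vector `c(loss = , gain = )` with `loss < 2 < gain`.
#' @export
derive_thresholds <- function(segments, min_bins = 5L, max_bins = 127L,
                              derive = TRUE,
                              defaults = c(loss = 1.29, gain = 2.80)) {
  if (!derive) return(defaults)
  seg <- segments[is_autosome(segments$chrom), , drop = FALSE]
  seg <- seg[seg$n_bins >= min_bins & seg$n_bins <= max_bins, , drop = FALSE]
  if (nrow(seg) < 20L) {
    warning("fewer than 20 eligible segments; using default thresholds")
    return(defaults)
  }
  cn <- seg$cn_est
  sub <- cn[cn < 1.5]
  dip <- cn[cn >= 1.5 & cn < 2.5]
  supra <- cn[cn >= 2.5]
  if (length(dip) == 0L) {
    warning("no diploid mode found; using default thresholds")
    return(defaults)
  }
  q <- function(v, p) unname(stats::quantile(v, p, names = FALSE))
  loss <- if (length(sub)) (q(sub, 0.995) + q(dip, 0.005)) / 2
  else (1 + q(dip, 0.005)) / 2
  gain <- if (length(supra)) (q(dip, 0.995) + q(supra, 0.005)) / 2
  else (q(dip, 0.995) + 3) / 2
  loss <- min(loss, 1.999)
  gain <- max(gain, 2.001)
  c(loss = loss, gain = gain)
}

#' Extract CNV calls from a cell's segmentation
#'
#' A segment becomes a call iff its copy-number estimate is at or below
#' the loss threshold or at or above the gain threshold, and it spans at
#' least `min_bins` bins.
#'
#' @param segset `segment_set` with copy numbers assigned.
#' @param loss_thr,gain_thr copy-number thresholds (`loss_thr < 2 <
#'   gain_thr`); defaults are the study values 1.29 and 2.80.
#' @param min_bins minimum call size in bins (default 5).
#' @param cell_id,individual_id,method labels attached to the calls.
#' @return data.frame of calls: `chrom`, `start`, `end`, `type`
#'   (`gain`/`loss`), `cn_int`, `cn_est`, `n_bins`, `cell_id`,
#'   `individual_id`, `method`.
#' @export
extract_cnvs <- function(segset, loss_thr = 1.29, gain_thr = 2.80,
                         min_bins = 5L, cell_id = NA_character_,
                         individual_id = NA_character_,
                         method = NA_character_) {
  stopifnot(loss_thr < 2, gain_thr > 2)
  seg <- if (is.data.frame(segset)) segset else segset$segments
  hit <- (seg$cn_est <= loss_thr | seg$cn_est >= gain_thr) &
    seg$n_bins >= min_bins
  seg <- seg[hit, , drop = FALSE]
  if (nrow(seg) == 0L) return(empty_calls())
  if (is.null(cell_id)) cell_id <- NA_character_
  if (is.null(individual_id)) individual_id <- NA_character_
  if (is.null(method)) method <- NA_character_
  data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
             type = ifelse(seg$cn_est <= loss_thr, "loss", "gain"),
             cn_int = seg$cn_int, cn_est = seg$cn_est, n_bins = seg$n_bins,
             cell_id = cell_id, individual_id = individual_id,
             method = method, row.names = NULL)
}

empty_calls <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             type = character(), cn_int = integer(), cn_est = numeric(),
             n_bins = integer(), cell_id = character(),
             individual_id = character(), method = character())
}

#' Segment and call one cell
#'
#' Convenience wrapper: CBS, ploidy fit, copy-number assignment, call
#' extraction.
#'
#' @inheritParams cbs_segment
#' @inheritParams extract_cnvs
#' @param profile a [cell_profile()]; its `corrected` ratios are used
#'   unless `values` overrides them (e.g. denoised ratios).
#' @param values optional replacement ratio vector.
#' @return list with `segments` (`segment_set`) and `calls`.
#' @export
call_cell <- function(profile, values = NULL, alpha = 0.01, min_width = 5L,
                      n_perm = 10000L, rng_seed = 1L, loss_thr = 1.29,
                      gain_thr = 2.80, min_bins = 5L) {
  v <- if (is.null(values)) profile$corrected else values
  segset <- cbs_segment(v, profile$bins, alpha = alpha,
                        min_width = min_width, n_perm = n_perm,
                        rng_seed = rng_seed)
  segset <- assign_copy_number(segset, fit_ploidy(segset))
  calls <- extract_cnvs(segset, loss_thr, gain_thr, min_bins,
                        cell_id = profile$cell_id,
                        individual_id = profile$individual_id,
                        method = profile$method)
  list(segments = segset, calls = calls)
}
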