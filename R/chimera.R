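#' Classify read-pair orientation
#'
#' In clean paired-end data both mates point inward, towards each other.
#' Whole-genome amplification creates chimeric junctions whose signatures
#' are discordant orientations: outward pairs (tandem-duplication-like),
#' same-strand pairs (inversion-like, "other"), and mates on different
#' chromosomes (translocation-like). Classification is symmetric under
#' mate swap; mates at the same position are ordered with the + strand
#' first (which makes discordant-strand ties inward and same-strand ties
#' other).
#'
#' @param pairs data.frame with `chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2` (strands `"+"`/`"-"`).
#' @return character vector in `{inward, outward, interchrom, other}`,
#'   `NA` for records with missing strand or chromosome.
#' @export
classify_pairs <- function(pairs) {
  with(pairs, {
    ok <- !is.na(strand1) & !is.na(strand2) & strand1 %in% c("+", "-") &
      strand2 %in% c("+", "-") & !is.na(chrom1) & !is.na(chrom2)
    inter <- chrom1 != chrom2
    first_is_left <- pos1 < pos2 | (pos1 == pos2 & strand1 == "+")
    sL <- ifelse(first_is_left, strand1, strand2)
    sR <- ifelse(first_is_left, strand2, strand1)
    out <- ifelse(inter, "interchrom",
                  ifelse(sL == sR, "other",
                         ifelse(sL == "+", "inward", "outward")))
    out[!ok] <- NA_character_
    out
  })
}

#' Per-cell chimera summary
#'
#' Fractions of read-pair orientation categories among classifiable
#' records, after optional mapping-quality filtering of both mates and
#' removal of records flagged as duplicates.
#'
#' @param pairs pair records for one cell (see [classify_pairs()];
#'   optional `mq1`, `mq2`, `is_dup` columns).
#' @param mq_min minimum mapping quality required of both mates.
#' @return list with `fractions` (named, sums to 1 over inward/outward/
#'   interchrom/other), `n_classified` and `n_unclassifiable`.
#' @export
summarize_chimeras <- function(pairs, mq_min = 0) {
  if (!is.null(pairs$is_dup)) pairs <- pairs[!pairs$is_dup, , drop = FALSE]
  if (!is.null(pairs$mq1) && mq_min > 0)
    pairs <- pairs[pairs$mq1 >= mq_min & pairs$mq2 >= mq_min, , drop = FALSE]
  cls <- if (nrow(pairs)) classify_pairs(pairs) else character(0)
  n_bad <- sum(is.na(cls))
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L) stop("no classifiable read pairs")
  cats <- c("inward", "outward", "interchrom", "other")
  frac <- table(factor(cls, cats)) / length(cls)
  list(fractions = stats::setNames(as.numeric(frac), cats),
       n_classified = length(cls), n_unclassifiable = n_bad)
}
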