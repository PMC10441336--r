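# Shared fixtures: small bin schemes and cohorts built in code.

flat_bins <- function(n, chrom = "chr1", width = 250e3) {
  build_bins(stats::setNames(n * width, chrom), "fixed", width)
}

# n bins split over several autosomes, with a reproducible GC column.
multi_chrom_bins <- function(n_per = 50, chroms = paste0("chr", 1:4),
                             width = 250e3, gc_seed = 11) {
  g <- stats::setNames(rep(n_per * width, length(chroms)), chroms)
  b <- build_bins(g, "fixed", width)
  set.seed(gc_seed)
  b$gc <- pmin(0.6, pmax(0.3, stats::rnorm(nrow(b), 0.42, 0.05)))
  b
}

small_cohort <- function(n = 6, method = "picoplex", individual = "I1",
                         prefix = "C") {
  data.frame(cell_id = sprintf("%s%02d", prefix, seq_len(n)),
             individual_id = individual, method = method)
}

# Quiet profile for fast deterministic simulations.
quiet_profiles <- function(sd = 0.05) {
  p <- wga_default_profiles()
  for (m in names(p)) {
    p[[m]]$bin_noise_sd <- sd
    p[[m]]$artifact_amplitude <- 0
    p[[m]]$gc_slope <- 0
    p[[m]]$dropout_rate <- 0
  }
  p
}

# Brute-force max-t arc oracle mirroring the segmentation constraints.
brute_best_arc <- function(x, min_width) {
  n <- length(x)
  S <- c(0, cumsum(x))
  best <- list(stat = -1, i = NA, j = NA)
  for (i in 0:(n - min_width)) {
    if (i > 0 && i < min_width) next
    for (j in (i + min_width):n) {
      if (j < n && n - j < min_width) next
      m <- j - i
      if (n - m < min_width) next
      d <- (S[j + 1] - S[i + 1]) / m - (S[n + 1] - S[j + 1] + S[i + 1]) / (n - m)
      stat <- abs(d) * sqrt(m * (n - m))
      if (stat > best$stat) best <- list(stat = stat, i = i, j = j)
    }
  }
  best
}

# Exact two-sided Fisher p by full hypergeometric enumeration.
brute_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  pr <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
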