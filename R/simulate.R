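#' WGA chemistry noise profile
#'
#' Bundles the parameters that control how a simulated amplification
#' chemistry distorts binned read depth: white multiplicative bin noise,
#' shared low-frequency artifact tracks, a GC-coverage response, locus
#' dropout, and the chemistry's discordant read-pair mixture.
#'
#' The bundled defaults ([wga_default_profiles()]) are calibrated so that
#' simulated cohorts reproduce the published per-chemistry evenness scores
#' (neighbour-difference MAD means of about 0.15 for PicoPLEX, 0.24 for PTA
#' and 0.57 for dMDA at the default depth) and the qualitative ordering of
#' chimeric read-pair classes between chemistries.
#'
#' @param name chemistry label: `"picoplex"`, `"pta"` or `"dmda"`.
#' @param bin_noise_sd sd of the lognormal multiplicative per-bin noise
#'   (dimensionless) at the 500 kb reference bin size. 0 switches the
#'   generator to its deterministic noise-free limit (no Poisson sampling
#'   either). Amplification noise acts at amplicon scale, so it partially
#'   averages out in larger bins: the effective sd scales as
#'   `(bin_size / noise_ref_bin_bp)^-noise_size_exponent`, matching the
#'   observed improvement of MAD with growing bin size.
#' @param noise_size_exponent bin-size averaging exponent (0 = no
#'   averaging, 0.5 = independent sub-blocks; default 0.3).
#' @param noise_ref_bin_bp bin size at which `bin_noise_sd` is quoted
#'   (500 kb, the size at which the published per-chemistry scores were
#'   measured).
#' @param artifact_amplitude sd of per-cell loadings on the shared
#'   low-frequency artifact tracks.
#' @param n_artifact_components number of shared tracks per individual.
#' @param gc_slope log-linear coverage-vs-GC effect; negative values drop
#'   coverage in GC-rich bins.
#' @param dropout_rate fraction of bins with complete amplification failure
#'   (zero depth).
#' @param pair_mix named proportions over `inward`, `outward`, `interchrom`,
#'   `other` read-pair orientations.
#' @return list of class `wga_profile`.
#' @export
wga_profile <- function(name, bin_noise_sd, artifact_amplitude = 0,
                        n_artifact_components = 3L, gc_slope = 0,
                        dropout_rate = 0,
                        pair_mix = c(inward = 1, outward = 0,
                                     interchrom = 0, other = 0),
                        noise_size_exponent = 0.3,
                        noise_ref_bin_bp = 500e3) {
  stopifnot(bin_noise_sd >= 0, dropout_rate >= 0, dropout_rate < 1,
            n_artifact_components >= 0, all(pair_mix >= 0),
            noise_size_exponent >= 0, noise_ref_bin_bp > 0)
  pair_mix <- pair_mix / sum(pair_mix)
  structure(list(name = name, bin_noise_sd = bin_noise_sd,
                 artifact_amplitude = artifact_amplitude,
                 n_artifact_components = as.integer(n_artifact_components),
                 gc_slope = gc_slope, dropout_rate = dropout_rate,
                 pair_mix = pair_mix,
                 noise_size_exponent = noise_size_exponent,
                 noise_ref_bin_bp = noise_ref_bin_bp),
            class = "wga_profile")
}

#' Default per-chemistry profiles
#'
#' Noise scales are ordered picoplex < pta < dmda; pair mixtures follow the
#' observed orderings (outward pairs most frequent in PicoPLEX and least in
#' PTA; inter-chromosomal pairs most frequent in PTA and least in dMDA;
#' other orientations frequent in PTA and dMDA, rare in PicoPLEX).
#'
#' @return named list of [wga_profile()] objects.
#' @export
wga_default_profiles <- function() {
  list(
    picoplex = wga_profile("picoplex", bin_noise_sd = 0.097,
                           artifact_amplitude = 0.015, gc_slope = -0.2,
                           dropout_rate = 0.002,
                           pair_mix = c(inward = 0.955, outward = 0.040,
                                        interchrom = 0.004, other = 0.001)),
    pta = wga_profile("pta", bin_noise_sd = 0.163,
                      artifact_amplitude = 0.05, gc_slope = -0.6,
                      dropout_rate = 0.01,
                      pair_mix = c(inward = 0.975, outward = 0.004,
                                   interchrom = 0.006, other = 0.015)),
    dmda = wga_profile("dmda", bin_noise_sd = 0.436,
                       artifact_amplitude = 0.30, gc_slope = -0.8,
                       dropout_rate = 0.05,
                       pair_mix = c(inward = 0.970, outward = 0.015,
                                    interchrom = 0.002, other = 0.013))
  )
}

#' Scaled-down synthetic genome
#'
#' Eight autosomes (24-50 Mb, 278 Mb total) and optionally a 30 Mb chrX;
#' small enough that permutation-based segmentation of whole cohorts runs
#' at desk scale while every chromosome still holds many bins at 250 kb.
#'
#' @param include_chrX add a chrX (halved depth in male cells).
#' @return named vector of chromosome lengths (bp).
#' @export
synthetic_genome <- function(include_chrX = FALSE) {
  g <- c(chr1 = 50e6, chr2 = 45e6, chr3 = 40e6, chr4 = 35e6,
         chr5 = 30e6, chr6 = 28e6, chr7 = 26e6, chr8 = 24e6)
  if (include_chrX) g <- c(g, chrX = 30e6)
  g
}

#' Cohort simulation specification
#'
#' @param cells data.frame with columns `cell_id`, `individual_id`,
#'   `method` and optionally `sex` (`"female"` default; `"male"` halves
#'   chrX depth).
#' @param genome named chromosome-length vector.
#' @param bin_size bin width in bp (250 kb default, the PicoPLEX calling
#'   resolution; 500 kb is used for PTA).
#' @param mean_reads_per_bin expected autosomal diploid depth per bin
#'   (200 by default, i.e. shallow WGS at roughly 0.08x with 100 bp reads
#'   and 250 kb bins).
#' @param cnv_menu data.frame of plantable private events: `size_bp`, `cn`
#'   (integer, not 2), `frequency` (per-cell probability of carrying one).
#' @param shared_cnvs optional data.frame of recurrent artifact-like events
#'   (`chrom`, `start`, `end`, `cn`, `scope` in `"individual"`/`"cohort"`,
#'   `carrier_frac`, optional `individual`) planted into a sampled fraction
#'   of cells; these emulate the recurrent calls the artifact filter must
#'   remove.
#' @param shared_artifact_seed seed for the shared low-frequency tracks.
#' @param rng_seed master seed; all cell-level streams are derived from it
#'   by stable hashing of cell ids, so results do not depend on cell order.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(cells, genome = synthetic_genome(),
                        bin_size = 250e3, mean_reads_per_bin = 200,
                        cnv_menu = default_cnv_menu(), shared_cnvs = NULL,
                        shared_artifact_seed = 1L, rng_seed = 1L) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "individual_id", "method") %in% names(cells)),
            !anyDuplicated(cells$cell_id),
            bin_size > 0, mean_reads_per_bin > 0)
  if (is.null(cells$sex)) cells$sex <- "female"
  if (!is.null(cnv_menu) && nrow(cnv_menu)) {
    stopifnot(all(c("size_bp", "cn", "frequency") %in% names(cnv_menu)),
              all(cnv_menu$cn != 2), all(cnv_menu$cn >= 0),
              all(cnv_menu$frequency >= 0))
  }
  structure(list(cells = cells, genome = genome, bin_size = bin_size,
                 mean_reads_per_bin = mean_reads_per_bin,
                 cnv_menu = cnv_menu, shared_cnvs = shared_cnvs,
                 shared_artifact_seed = as.integer(shared_artifact_seed),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Default planted-event menu
#'
#' Mb-scale gains and losses (3-8 Mb, CN 1 and 3) at frequencies giving
#' roughly 1.6 private events per cell; sizes stay well above the 5-bin
#' calling floor at 250-500 kb bins.
#' @return data.frame.
#' @export
default_cnv_menu <- function() {
  data.frame(size_bp = c(5e6, 5e6, 8e6, 3e6),
             cn = c(1L, 3L, 3L, 1L),
             frequency = c(0.5, 0.5, 0.3, 0.3))
}

# Deterministic 31-adic string hash into [0, 2^31 - 2].
stable_hash <- function(s) {
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

derive_seed <- function(base, label) {
  as.integer((as.numeric(base) * 48271 + stable_hash(label)) %% 2147483647)
}

# Run fn under a derived seed, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

# Smooth AR(1) GC track around 0.42, clipped to [0.30, 0.60].
simulate_gc <- function(bins, seed, mean_gc = 0.42, sd_gc = 0.05, phi = 0.5) {
  with_seed(seed, function() {
    gc <- numeric(nrow(bins))
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      n <- length(idx)
      e <- stats::rnorm(n, 0, sd_gc * sqrt(1 - phi^2))
      z <- numeric(n); z[1] <- stats::rnorm(1, 0, sd_gc)
      for (i in seq_len(n - 1)) z[i + 1] <- phi * z[i] + e[i + 1]
      gc[idx] <- pmin(0.60, pmax(0.30, mean_gc + z))
    }
    gc
  })
}

# k shared artifact tracks: unit-sd sinusoid mixtures over genomic
# position, with Mb-scale wavelengths so the waves recur at the scale of
# amplification bias rather than of whole chromosomes.
artifact_tracks <- function(pos_bp, k, seed,
                            wavelength_bp = c(8e6, 20e6)) {
  n_bins <- length(pos_bp)
  if (k == 0L) return(matrix(0, n_bins, 0))
  with_seed(seed, function() {
    sapply(seq_len(k), function(j) {
      wl <- stats::runif(3, wavelength_bp[1], wavelength_bp[2])
      a <- stats::runif(3, 0.5, 1)
      ph <- stats::runif(3, 0, 2 * pi)
      tr <- a[1] * sin(2 * pi * pos_bp / wl[1] + ph[1]) +
        a[2] * sin(2 * pi * pos_bp / wl[2] + ph[2]) +
        a[3] * sin(2 * pi * pos_bp / wl[3] + ph[3])
      tr / stats::sd(tr)
    })
  })
}

#' Simulate a single-cell WGA cohort
#'
#' Generates per-cell binned read counts with the statistical structure the
#' downstream analysis assumes: Poisson sampling around a diploid baseline,
#' lognormal multiplicative bin noise, shared low-frequency artifact tracks
#' per individual (with per-cell loadings), a log-linear GC response, locus
#' dropout, and planted Mb-scale gains/losses recorded in a ground-truth
#' table. With `bin_noise_sd = 0` (and no other noise sources) the
#' generator returns its deterministic expected counts.
#'
#' @param spec a [cohort_spec()].
#' @param profiles named list of [wga_profile()]s covering every method in
#'   `spec$cells$method`.
#' @return list with `counts` (bins x cells integer matrix), `truth`
#'   (data.frame `cell_id`, `chrom`, `start`, `end`, `cn`, `shared`),
#'   `bins` (`bin_scheme` with simulated GC), `cells`, and `spec`.
#' @export
simulate_cohort <- function(spec, profiles = wga_default_profiles()) {
  stopifnot(inherits(spec, "cohort_spec"))
  missing <- setdiff(unique(spec$cells$method), names(profiles))
  if (length(missing))
    stop("no profile for method(s): ", paste(missing, collapse = ", "))

  bins <- build_bins(spec$genome, "fixed", spec$bin_size)
  bins$gc <- simulate_gc(bins, derive_seed(spec$rng_seed, "gc"))
  n_bins <- nrow(bins)
  cells <- spec$cells
  auto <- is_autosome(bins)

  k_max <- max(vapply(profiles[unique(cells$method)],
                      function(p) p$n_artifact_components, integer(1)))
  chrom_off <- c(0, cumsum(as.numeric(spec$genome)))[
    match(bins$chrom, names(spec$genome))]
  pos_bp <- chrom_off + (bins$start + bins$end) / 2
  tracks <- lapply(unique(cells$individual_id), function(ind) {
    artifact_tracks(pos_bp, k_max,
                    derive_seed(spec$shared_artifact_seed, paste0("tracks:", ind)))
  })
  names(tracks) <- unique(cells$individual_id)

  shared_truth <- plant_shared_cnvs(spec)
  truth_list <- list()
  counts <- matrix(0L, n_bins, nrow(cells),
                   dimnames = list(NULL, cells$cell_id))

  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    prof <- profiles[[cell$method]]
    seed <- derive_seed(spec$rng_seed, paste0("cell:", cell$cell_id))
    res <- with_seed(seed, function() {
      simulate_cell(cell, prof, spec, bins, auto,
                    tracks[[cell$individual_id]],
                    shared_truth[shared_truth$cell_id == cell$cell_id, , drop = FALSE])
    })
    counts[, ci] <- res$counts
    truth_list[[ci]] <- res$truth
  }
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  list(counts = counts, truth = truth, bins = bins, cells = cells, spec = spec)
}

# Sample carriers for recurrent artifact-like events (deterministic).
plant_shared_cnvs <- function(spec) {
  empty <- data.frame(cell_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), cn = integer(),
                      shared = logical())
  sc <- spec$shared_cnvs
  if (is.null(sc) || nrow(sc) == 0L) return(empty)
  cells <- spec$cells
  rows <- lapply(seq_len(nrow(sc)), function(i) {
    ev <- sc[i, ]
    pool <- if (identical(ev$scope, "individual")) {
      ind <- if (!is.null(sc$individual) && !is.na(ev$individual))
        ev$individual else cells$individual_id[1]
      cells$cell_id[cells$individual_id == ind]
    } else cells$cell_id
    n_carry <- max(1L, ceiling(ev$carrier_frac * length(pool)))
    carriers <- with_seed(derive_seed(spec$rng_seed, paste0("shared:", i)),
                          function() sample(pool, n_carry))
    data.frame(cell_id = carriers, chrom = ev$chrom, start = ev$start,
               end = ev$end, cn = as.integer(ev$cn), shared = TRUE)
  })
  do.call(rbind, rows)
}

# One cell's counts + truth; runs inside the cell's seeded stream.
simulate_cell <- function(cell, prof, spec, bins, auto, tracks, shared_rows) {
  n_bins <- nrow(bins)
  cn <- rep(2, n_bins)
  if (identical(cell$sex, "male")) cn[!auto] <- 1

  truth <- plant_private_cnvs(cell$cell_id, spec, bins, auto)
  if (nrow(shared_rows)) truth <- rbind(truth, shared_rows)
  for (i in seq_len(nrow(truth))) {
    hit <- bins$chrom == truth$chrom[i] &
      bins$start >= truth$start[i] & bins$end <= truth$end[i]
    cn[hit] <- truth$cn[i]
  }

  noise_free <- prof$bin_noise_sd == 0 && prof$artifact_amplitude == 0 &&
    prof$gc_slope == 0 && prof$dropout_rate == 0
  fac <- rep(1, n_bins)
  if (prof$gc_slope != 0) {
    g <- pmin(3, pmax(0.2, exp(prof$gc_slope * (bins$gc - 0.42))))
    fac <- fac * g / mean(g)
  }
  k <- prof$n_artifact_components
  if (prof$artifact_amplitude > 0 && k > 0) {
    # additive track mixture on the depth-ratio scale: the linear latent
    # structure that principal-component regression removes exactly
    w <- stats::rnorm(k, 0, prof$artifact_amplitude)
    a <- pmax(0.05, 1 + as.vector(tracks[, seq_len(k), drop = FALSE] %*% w))
    fac <- fac * a / mean(a)
  }
  if (prof$bin_noise_sd > 0) {
    s <- prof$bin_noise_sd *
      (spec$bin_size / prof$noise_ref_bin_bp)^(-prof$noise_size_exponent)
    fac <- fac * exp(stats::rnorm(n_bins, 0, s) - s^2 / 2)
  }
  if (prof$dropout_rate > 0)
    fac[stats::runif(n_bins) < prof$dropout_rate] <- 0

  mu <- spec$mean_reads_per_bin * (cn / 2) * fac
  raw <- if (noise_free) as.integer(round(mu)) else stats::rpois(n_bins, mu)
  list(counts = raw, truth = truth)
}

plant_private_cnvs <- function(cell_id, spec, bins, auto) {
  out <- data.frame(cell_id = character(), chrom = character(),
                    start = numeric(), end = numeric(), cn = integer(),
                    shared = logical())
  menu <- spec$cnv_menu
  if (is.null(menu) || nrow(menu) == 0L) return(out)
  chroms <- names(spec$genome)[is_autosome(names(spec$genome))]
  lens <- spec$genome[chroms]
  taken <- list()
  for (i in seq_len(nrow(menu))) {
    if (stats::runif(1) >= menu$frequency[i]) next
    for (try in 1:30) {
      ch <- sample(chroms, 1, prob = lens)
      idx <- which(bins$chrom == ch)
      # menu sizes at or above the chromosome length plant a whole-
      # chromosome aneusomy
      size_bins <- min(max(1L, round(menu$size_bp[i] / spec$bin_size)),
                       length(idx))
      b0 <- if (size_bins == length(idx)) 1L
      else sample(length(idx) - size_bins, 1)
      s <- bins$start[idx[b0]]
      e <- bins$end[idx[b0 + size_bins - 1L]]
      clash <- any(vapply(taken, function(tk)
        tk$chrom == ch && s < tk$end && e > tk$start, logical(1)))
      if (!clash) {
        taken[[length(taken) + 1L]] <- list(chrom = ch, start = s, end = e)
        out <- rbind(out, data.frame(cell_id = cell_id, chrom = ch,
                                     start = s, end = e,
                                     cn = as.integer(menu$cn[i]),
                                     shared = FALSE))
        break
      }
    }
  }
  out
}

#' Simulate discordant/concordant read-pair records
#'
#' Draws pair orientations from a category mixture and generates coordinate
#' and strand fields consistent with each category: `inward` proper pairs
#' (leftmost mate on +), `outward` tandem-duplication-like pairs, `other`
#' same-strand inversion-like pairs, and `interchrom` translocation-like
#' pairs on different chromosomes. Mate order is randomised so classifiers
#' cannot rely on it.
#'
#' @param n_pairs number of records.
#' @param mix named non-negative proportions over the four categories
#'   (normalised to sum 1).
#' @param rng_seed seed.
#' @param chroms,chrom_len chromosome labels and common length used for
#'   coordinates.
#' @return data.frame with `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'   `strand2`, `mq1`, `mq2`, `is_dup` and the generating `category`.
#' @export
simulate_pairs <- function(n_pairs, mix, rng_seed = 1L,
                           chroms = paste0("chr", 1:4), chrom_len = 50e6) {
  cats <- c("inward", "outward", "interchrom", "other")
  if (any(mix < 0)) stop("negative proportion in mix")
  m <- stats::setNames(numeric(4), cats)
  m[names(mix)] <- mix
  if (sum(m) <= 0) stop("mix sums to zero")
  m <- m / sum(m)
  empty <- data.frame(chrom1 = character(), pos1 = numeric(),
                      strand1 = character(), chrom2 = character(),
                      pos2 = numeric(), strand2 = character(),
                      mq1 = numeric(), mq2 = numeric(), is_dup = logical(),
                      category = character())
  if (n_pairs == 0L) return(empty)
  with_seed(as.integer(rng_seed), function() {
    cat <- sample(cats, n_pairs, replace = TRUE, prob = m)
    c1 <- sample(chroms, n_pairs, replace = TRUE)
    posL <- floor(stats::runif(n_pairs, 0, chrom_len - 2e6))
    d <- ifelse(cat == "inward", floor(stats::runif(n_pairs, 200, 600)),
                floor(stats::runif(n_pairs, 1e4, 1e6)))
    posR <- posL + d
    c2 <- c1
    ic <- cat == "interchrom"
    if (any(ic)) {
      c2[ic] <- vapply(c1[ic], function(ch)
        sample(setdiff(chroms, ch), 1), character(1))
      posR[ic] <- floor(stats::runif(sum(ic), 0, chrom_len))
    }
    sL <- rep("+", n_pairs); sR <- rep("-", n_pairs)
    sL[cat == "outward"] <- "-"; sR[cat == "outward"] <- "+"
    same <- sample(c("+", "-"), n_pairs, replace = TRUE)
    sL[cat == "other"] <- same[cat == "other"]
    sR[cat == "other"] <- same[cat == "other"]
    rnd <- sample(c("+", "-"), n_pairs, replace = TRUE)
    sR[ic] <- rnd[ic]
    swap <- stats::runif(n_pairs) < 0.5
    out <- data.frame(
      chrom1 = ifelse(swap, c2, c1), pos1 = ifelse(swap, posR, posL),
      strand1 = ifelse(swap, sR, sL),
      chrom2 = ifelse(swap, c1, c2), pos2 = ifelse(swap, posL, posR),
      strand2 = ifelse(swap, sL, sR),
      mq1 = 60, mq2 = 60, is_dup = FALSE, category = cat)
    out
  })
}

#' Simulate per-cell read-pair sets for a cohort
#'
#' Each cell's orientation mixture is its chemistry's default jittered on
#' the log scale, emulating cell-to-cell variability in chimera burden.
#'
#' @param cells cohort manifest (`cell_id`, `method`).
#' @param n_pairs_per_cell records per cell.
#' @param profiles per-method [wga_profile()]s supplying `pair_mix`.
#' @param jitter_sd lognormal sd of the per-cell mixture jitter.
#' @param rng_seed master seed (split per cell by id hashing).
#' @return named list of per-cell record data.frames.
#' @export
simulate_pair_cohort <- function(cells, n_pairs_per_cell = 5000,
                                 profiles = wga_default_profiles(),
                                 jitter_sd = 0.15, rng_seed = 1L) {
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    mix <- profiles[[cell$method]]$pair_mix
    seed <- derive_seed(rng_seed, paste0("pairs:", cell$cell_id))
    jit <- with_seed(seed, function() exp(stats::rnorm(length(mix), 0, jitter_sd)))
    mix <- mix * jit
    simulate_pairs(n_pairs_per_cell, mix / sum(mix), rng_seed = seed %% 2000000000)
  })
  stats::setNames(out, cells$cell_id)
}
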