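#' PCA denoising of a read-depth matrix
#'
#' Removes read-depth variation shared across cells — amplification and
#' binning artifacts that recur at the same genomic positions — while
#' preserving copy-number events private to single cells. Principal
#' components are computed over bins (bins as observations, cells as
#' variables), giving genome-length "artifact tracks"; each cell's profile
#' is regressed on the leading tracks and its residuals (recentred at
#' ratio 1) replace the input.
#'
#' Three safeguards keep cell-private signal intact and stop the procedure
#' from trading shared artifact for fresh noise:
#' \itemize{
#'   \item components for each cell are computed from the *other* cells
#'     only (leave-one-out): a strong CNV private to one cell would
#'     otherwise leak into the leading components and be partially
#'     regressed away;
#'   \item only components whose eigenvalue exceeds the Marchenko-Pastur
#'     upper edge of the noise bulk count as shared variation;
#'     `variance_fraction` selects the smallest leading subset of those
#'     supra-noise components reaching that share of their pooled
#'     variance. On a pure-white-noise cohort no component qualifies and
#'     the input is returned unchanged, and regression on bulk-noise
#'     components (which would inject other cells' bin noise) is avoided;
#'   \item zero-depth dropout bins are imputed to the cell median before
#'     the PCA and excluded from each cell's regression, so locus dropout
#'     neither contaminates the tracks nor steers the fit;
#'   \item tracks are smoothed with a short running mean before the
#'     regression. An estimated track carries a white remnant of the
#'     contributing cells' bin noise on top of the low-frequency artifact
#'     wave-form, and in neighbour-difference space that white remnant is
#'     amplified several-fold relative to the wave-form, so regressing on
#'     raw tracks trades artifact for fresh bin-to-bin noise (the
#'     evenness score would worsen even as overall variance improves).
#' }
#'
#' @param mat bins x cells matrix of corrected depth ratios (>= 3 cells).
#' @param variance_fraction fraction of the supra-noise (shared) variance
#'   to remove, in (0, 1); the analysis sweeps 0.4 to 0.9 in 0.1 steps.
#' @param dropout_threshold ratios below this are treated as locus
#'   dropout (default 0.1).
#' @param track_smooth running-mean window (bins, odd) applied to each
#'   track before the regression; 1 disables smoothing.
#' @return matrix of the same shape: per-cell residuals + 1.
#' @export
pca_denoise <- function(mat, variance_fraction = 0.4,
                        dropout_threshold = 0.1, track_smooth = 3L) {
  stopifnot(is.matrix(mat))
  n_cells <- ncol(mat)
  n_bins <- nrow(mat)
  if (n_cells < 3L) stop("need at least 3 cells")
  if (variance_fraction <= 0 || variance_fraction >= 1)
    stop("variance_fraction must be in (0, 1)")
  # impute dropout bins to the bin's cross-cell median, which carries the
  # shared artifact level at that locus (a cell-level constant would not)
  bin_med <- apply(mat, 1, stats::median)
  clean <- mat
  for (j in seq_len(n_cells)) {
    bad <- mat[, j] < dropout_threshold
    if (any(bad) && !all(bad)) clean[bad, j] <- bin_med[bad]
  }
  out <- mat
  for (j in seq_len(n_cells)) {
    pc <- stats::prcomp(clean[, -j, drop = FALSE], center = TRUE,
                        scale. = FALSE)
    lambda <- pc$sdev^2
    k <- n_shared_components(lambda, n_bins, n_cells - 1L,
                             variance_fraction)
    if (k == 0L) next                       # nothing systematic to remove
    tracks <- pc$x[, seq_len(k), drop = FALSE]
    if (track_smooth > 1L)
      tracks <- apply(tracks, 2, running_mean, w = track_smooth)
    y <- mat[, j]
    ok <- y >= dropout_threshold
    fit <- stats::lm.wfit(cbind(1, tracks), y, as.numeric(ok))
    # dropout bins are excluded from the fit but recentred like the rest,
    # so their neighbourhoods keep the same contrast as before denoising
    out[, j] <- y - as.vector(cbind(1, tracks) %*% fit$coefficients) + 1
  }
  dimnames(out) <- dimnames(mat)
  out
}

# Centered running mean with shrinking windows at the edges.
running_mean <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Number of leading components to regress out: components above the
# Marchenko-Pastur upper edge of the noise bulk are "shared"; take the
# smallest leading set covering `fraction` of their pooled variance.
n_shared_components <- function(lambda, n_bins, n_cells, fraction) {
  if (all(lambda <= 0)) return(0L)
  sigma2 <- stats::median(lambda)
  edge <- 1.05 * sigma2 * (1 + sqrt(n_cells / n_bins))^2
  sig <- which(lambda > edge)
  if (length(sig) == 0L) return(0L)
  lam_sig <- lambda[sig]
  k <- which(cumsum(lam_sig) / sum(lam_sig) >= fraction)[1]
  min(k, length(sig))
}

#' Denoising sweep over the variance grid
#'
#' Runs [pca_denoise()] at each fraction of the standard 40-90% grid and
#' reports the mean cohort MAD before and after.
#'
#' @param mat bins x cells corrected-ratio matrix.
#' @param bins matching `bin_scheme`.
#' @param fractions variance grid (default `seq(0.4, 0.9, 0.1)`).
#' @return list with `residuals` (named list of matrices per fraction) and
#'   `mad_table` (data.frame `fraction`, `mean_mad`; fraction 0 = input).
#' @export
denoise_sweep <- function(mat, bins, fractions = seq(0.4, 0.9, by = 0.1)) {
  mean_mad <- function(m)
    mean(apply(m, 2, compute_mad, bins = bins))
  res <- lapply(fractions, function(f) pca_denoise(mat, f))
  names(res) <- sprintf("%.1f", fractions)
  tab <- data.frame(fraction = c(0, fractions),
                    mean_mad = c(mean_mad(mat),
                                 vapply(res, mean_mad, numeric(1))))
  list(residuals = res, mad_table = tab)
}
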