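---
title: "Single-cell WGA copy-number calling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell WGA copy-number calling: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scwgacnv)
```

# The problem

Single nuclei carry picograms of DNA, so shallow whole-genome sequencing
of a single cell requires whole-genome amplification (WGA). Every WGA
chemistry amplifies unevenly: PicoPLEX (hybrid PCR) is the most even,
primary template-directed amplification (PTA) intermediate, and droplet
MDA (dMDA) by far the noisiest. Unevenness is what limits read-depth
copy-number calling — an under-amplified region is indistinguishable,
locally, from a genuine loss. This package implements the full analysis
path for such data: genomic binning, fragment counting with
mapping-quality filtering, GC correction, per-cell evenness QC, removal
of read-depth variation shared across cells, circular binary
segmentation, integer copy-number calling with configurable gain/loss
thresholds, multi-cell artifact filtering, chimeric read-pair
classification, and cohort summaries — together with a synthetic cohort
generator that reproduces the statistical structure each step assumes,
so the entire pipeline is exercised and validated end to end without
access to controlled human data.

# The synthetic cohort generator

`simulate_cohort()` draws per-bin counts as Poisson around

\[
\mu_b \;=\; R \cdot \frac{cn_b}{2}\cdot g(\mathrm{gc}_b)\cdot
\Big(1+\textstyle\sum_k w_k T_k(b)\Big)\cdot e^{\varepsilon_b - s^2/2},
\]

with `R` the expected diploid depth per bin, `cn_b` the (planted) copy
number, `g` a log-linear GC response clipped to `[0.2, 3]`,
`T_k` shared sinusoid-mixture artifact tracks per individual with
per-cell loadings `w_k ~ N(0, amplitude)`, and lognormal multiplicative
bin noise of scale `s`. Dropout sets a random fraction of bins to zero
depth. Design points worth stating explicitly:

* **Additive artifact tracks.** The shared component enters as
  `1 + sum(w T)` on the ratio scale, not as a log-scale factor. This is
  the linear latent structure that principal-component regression
  removes exactly; a multiplicative (`exp`) form has median factor
  below 1 after mean-normalisation, so even oracle removal *raises* a
  median-based evenness score — an instructive pathology, but not the
  model the denoiser assumes.
* **Mb-scale artifact wavelengths.** Track wavelengths are drawn in
  genomic coordinates (8-20 Mb), the scale at which amplification bias
  recurs across cells. At fine bins (250-500 kb) the waves contribute
  little to neighbour differences; at the coarse bins used for noisy
  chemistries they dominate them — matching the observation that shared
  structure, not white noise, is what denoising can remove.
* **Bin-size-dependent white noise.** Amplification noise acts at
  amplicon scale, so it partially averages within larger bins: the
  effective scale is `bin_noise_sd * (bin_size/500kb)^-0.3`. The
  exponent sits between no averaging (0) and independent sub-blocks
  (0.5); evenness therefore improves with growing bin size, as observed
  on real data.
* **Calibration.** The default profiles are calibrated so that
  20-cell cohorts at 500 kb bins reproduce the published per-chemistry
  evenness means — MAD about 0.15 (PicoPLEX), 0.24 (PTA) and 0.57
  (dMDA); 500 kb and ~0.1x depth (400 reads per 500 kb bin) is the
  condition at which those values were measured. Dropout rates (0.2%,
  1%, 5%) and GC slopes (-0.2, -0.6, -0.8) grade mildly from PicoPLEX
  to dMDA; the GC response is a slight high-GC droop.
* **Seeding.** One master seed is split per cell by a stable string
  hash of the cell id, so adding or reordering cells never changes
  another cell's data, and the same spec + seed is bit-reproducible.
* **Scaled-down genome.** The default genome is eight autosomes of
  24-50 Mb (278 Mb total, optional 30 Mb chrX at half depth in males).
  Permutation-based segmentation of full cohorts then runs in seconds
  to minutes while every chromosome still holds 96-200 bins at 250 kb.
  Analyses of chromosome-arm-scale events instead pass an 8 x 150 Mb
  genome to `cohort_spec()`.

What the generator does *not* emulate: sequence-context amplification
chemistry, read-level errors, mappability structure of a real reference,
centromeric/repeat artifacts, replication-timing waves tied to cell
state, or correlated dropout. Passing tests therefore demonstrate that
the pipeline's inferential machinery is correct under its stated
statistical assumptions — not that those assumptions exhaust real WGA
data.

# Per-cell QC

The central evenness score is the scaled median absolute deviation of
**neighbouring-bin differences** of the normalised profile
(`compute_mad`): differences are taken within chromosomes on autosomes
only, and the R consistency constant 1.4826 is applied (the source
analyses of this field run in R; the constant is switchable). Because
the median ignores the tails, a genuine CNV step of a few dozen bins
barely moves the score — the property that makes it an *amplification*
metric rather than a biology metric.

`lorenz_curve()` gives the cumulative read fraction against cumulative
genome fraction with its Gini coefficient. `confidence_score()` is a
length-weighted mean of `max(0, 1 - 2|cn - round(cn)|)` over autosomal
segments; it is **our reconstruction** — the upstream tools report such
a score without publishing a formula — chosen so that the customary
gate value (at least 0.7) separates profiles whose segments sit near
integers from intermediate-state profiles. The QC gate keeps cells with
MAD at most 0.3 and confidence at least 0.7, both boundaries inclusive.

# GC correction

`gc_correct()` fits LOWESS of normalised depth on GC (span 0.05, three
robustness iterations) and divides it out, rescaling the autosomal mean
to 1. Two robustness rules matter in practice: the trend is fitted on
autosomal bins only (sex chromosomes sit at another copy-number level
and would bend it), and the span is floored so that each local fit sees
at least 20 bins — on a scheme of only ~100 coarse bins a 5-point
window can collapse toward zero and explode the corrected ratio. With
fewer than 10 distinct GC values the correction is skipped.

# PCA denoising

`pca_denoise()` removes read-depth variation shared across cells.
Components are computed over bins (bins as observations, cells as
variables); the component scores are genome-length artifact tracks, and
each cell is replaced by the residual of a regression on the leading
tracks, recentred at ratio 1. Four safeguards, each adopted after a
diagnosed failure mode:

1. **Leave-one-out components.** A strong CNV private to one cell leaks
   into leading components computed on all cells and is partially
   regressed away; components computed from the other cells only cannot
   contain it.
2. **Noise-floor component selection.** Only components whose
   eigenvalue exceeds the Marchenko-Pastur upper edge of the noise bulk
   count as shared variation; `variance_fraction` (the 40-90% grid)
   selects the smallest leading subset of *those* reaching that share
   of their pooled variance. Without the floor, high grid values force
   regression of a 20-cell cohort on ~17 bulk-noise components — pure
   overfitting. On white-noise cohorts no component qualifies and the
   input passes through unchanged.
3. **Track smoothing.** An estimated track carries a white remnant of
   the contributing cells' bin noise on top of the artifact wave-form.
   In neighbour-difference space the white remnant is amplified several
   fold relative to the wave-form, so regressing on raw tracks trades
   artifact for fresh bin-to-bin noise even while total variance
   improves. A 3-bin running mean suppresses the remnant and keeps
   wave-forms of period of about 2 bins and above.
4. **Dropout handling.** Zero-depth bins are imputed to the per-bin
   cross-cell median (which carries the artifact level at that locus)
   before the PCA, excluded from the regression fit, and recentred with
   the rest of the profile — passing them through at zero while their
   neighbours recentre to 1 would inflate trough-adjacent differences.

For dMDA, direct read-depth calling is unreliable at any bin size; the
workflow routes dMDA through denoising at 1 Mb bins or larger, and the
validated claim is deliberately modest: denoising lowers cohort MAD at
every grid setting and does not cost recall of chromosome-arm-scale
(about 50-75 Mb) planted events, the size regime where dMDA calling
becomes feasible at all.

# Segmentation and calling

`cbs_segment()` implements circular binary segmentation per chromosome:
the candidate split is the arc maximising the two-sample t statistic
between arc and complement (`|mean_arc - mean_rest| sqrt(m(n-m))`,
pooled variance being arc-invariant), subject to every resulting
segment holding at least `min_width = 5` bins; it is accepted when its
permutation p-value is below `alpha = 0.01` and the accepted arc's
cutpoints recurse. The arc search is O(n^2) in compiled code. The
permutation test (default 10,000 permutations, R RNG, reproducible
under the supplied seed) is *curtailed*: it stops early once the
Clopper-Pearson 99.9% interval for the p-value falls entirely below or
above alpha, which typically resolves an accepted split in ~700
permutations at an additional decision-error probability of at most
1e-3 per test. The hybrid tail approximation used by the classical
DNAcopy implementation is deliberately not reproduced. Adjacent
segments with mean ratios closer than 0.05 are merged afterwards (a
stand-in for undo-splits pruning). Chromosomes shorter than twice the
minimum width are returned whole.

`fit_ploidy()` grid-searches 1.5-5.5 (step 0.05) for the multiplier
minimising the bin-weighted squared distance of segment ratios from
integers. Two parsimony rules break the free-scale degeneracy (any
profile fits ever better at ever higher ploidy): only segments of at
least 10 bins enter the fit, since a short noisy segment at a
fractional ratio is matched exactly by an inflated multiplier; and
among candidates within 30% of the minimal objective the smallest
ploidy wins, so noise-level objective differences never push a diploid
cell to tetraploid. `extract_cnvs()` emits a call when
the copy-number estimate is at or below the loss threshold or at or
above the gain threshold and the segment spans at least 5 bins. The
configured thresholds, 1.29 (loss) and 2.80 (gain), are the values the
source analysis read from its pooled segment histogram.
`derive_thresholds()` re-derives thresholds from data: pool per-segment
copy-number estimates from QC-passed cells (segment sizes 5-127 bins,
the upper cap being the smallest human chromosome at the reference bin
size), then place each threshold at the midpoint between the facing
tail quantiles (99.5th/0.5th percentile) of the flanking and diploid
modes; a missing flanking mode anchors at copy number 1 or 3, and
fewer than 20 eligible segments falls back to the configured defaults
with a warning. The exact histogram-reading rule of the original
analysis is unpublished; the mid-gap rule is our choice, and the
defaults remain configuration, not derivation.

# Artifact filtering

Calls are grouped as *shared* when same chromosome, same type, and both
start and end within a method tolerance (2.5 Mb PicoPLEX, 5 Mb PTA;
mixed pairs use the larger), with transitive closure. Groups spanning
at least half of the QC-passed cells of their individual — "half" is
interpreted within-individual — or two and more individuals are
removed wholesale: recurrence across cells indicates germline variants
or pipeline artifacts, and recurrence across individuals cannot be
somatic. Sub-telomeric calls are flagged within a window defaulting to
two bin widths of a chromosome end (no published definition exists).
`novel_region_gains()` keeps calls whose union-overlap with a BED of
assembly-specific sequence reaches 50% of the call span, the criterion
used for gains specific to a complete reference assembly.
`aneusomy_check()` promotes call sets of one type covering at least
95% of a chromosome to a single whole-chromosome event — modelled on
a real case where two large losses added up to a whole chromosome with
2.3 Mb spared.

# Chimeras

WGA creates artifactual junctions visible as discordant read-pair
orientations: with mates ordered by position (ties ordered + first),
`inward` is the proper orientation, `outward` (leftmost mate on minus)
is tandem-duplication-like, equal strands are inversion-like (`other`),
and different chromosomes translocation-like (`interchrom`).
Classification is symmetric under mate swap; duplicates are dropped
and an optional mapping-quality filter applies to both mates. The
default per-chemistry mixtures reproduce the qualitative orderings
observed on real nuclei — outward most frequent in PicoPLEX and least
in PTA; inter-chromosomal least frequent in dMDA; other orientations
rare in PicoPLEX — the published figures give no numeric fractions, so
the default magnitudes (a few percent discordant) are plausible rather
than calibrated.

# Cohort statistics

`fisher_exact()` and `rank_sum()` follow the R conventions of the
source analysis (`fisher.test`'s "probability at most observed"
two-sided rule; exact Mann-Whitney when `n1*n2 <= 400` and tie-free,
else normal approximation with tie and continuity corrections). The
test suite checks the Fisher p-values against full hypergeometric
enumeration, and reproduces the published group comparisons from the
printed counts: 8/23 vs 6/11 cells with CNVs gives p = 0.46, and 10/24
vs 3/10 gives p = 0.70. `summarize_cohort()` recomputes all
percentages from integer counts; from the published per-individual
table (34 passed cells, 13 with a CNV, 36 calls of which 23 gains) the
roll-up is 38.2% of cells with at least one CNV, 63.9% gains, and 2.8
calls per CNV-bearing cell.

# Problem sizes used in validation

The bundled tests and the acceptance script run, per invocation: 20-cell
cohorts per chemistry at 500 kb bins for calibration checks; a 20-cell
PicoPLEX cohort on the 278 Mb default genome at 250 kb bins for
end-to-end recovery (precision and recall at least 0.9 against the
truth table); 100 pure-noise segmentations of 200 bins for the
false-positive rate (at most 5% at alpha = 0.01); 20 replicate
24-cell two-individual cohorts for the artifact filter (100% removal of
planted recurrent events, at least 95% retention of private ones); a
24-cell dMDA cohort on an 8 x 150 Mb genome at 2.5 Mb bins across the
40-90% denoising grid; and 10,000-pair mixtures for the chimera
classifier (recovery within 0.02). These sizes are the package's
validation design: large enough for stable proportions, small enough to
re-run routinely.

# Known limitations

* The confidence score is a reconstruction; absolute values are
  comparable within this package only.
* Threshold derivation reproduces the published 1.29/2.80 only as
  configuration; the derivation rule is ours.
* The denoiser assumes shared variation is smooth at the scale of a few
  bins and linear in the tracks; sharp recurrent artifacts (e.g.
  centromeric spikes shared across cells) would be treated as signal.
* Recurrent *real* CNVs (germline, clonal) are indistinguishable from
  artifacts by the sharing filter and are removed by design.
* The permutation curtailment adds a bounded (1e-3) per-test decision
  error relative to exhaustive permutation.
* Ploidy is not identifiable from relative depth alone: a noisy cell can
  occasionally fit an inflated ploidy whose integer levels still score
  high confidence, yielding a spurious genome-wide gain profile. The
  parsimony rules make this rare but cannot exclude it; copy-number
  profiles of flagged cells deserve visual review, as they receive in
  practice.
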