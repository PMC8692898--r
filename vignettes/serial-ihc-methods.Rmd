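---
title: "Methods: serial-section IHC registration and tumor-microenvironment quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial-section IHC registration and tumor-microenvironment quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(serialihc)
```

## The problem

In gastric-cancer tissue, cancer-associated fibroblast (CAF) subsets, immune
cells and tumor cells occupy distinct spatial niches: extracellular-matrix
CAFs (eCAFs, POSTN-high) concentrate in the distal stroma, inflammatory CAFs
(iCAFs) in and around tumor glands and lymphoid-nodule-like structures, and
M2 macrophages (CD163+) track the eCAF-rich stroma. Because conventional IHC
stains one marker per slide, spatial relationships between markers can only
be read by cutting serial sections, staining each for one marker, and
computationally aligning the sections into a common coordinate frame. This
package implements that workflow end to end — registration, stain
separation, compartment and tile-level quantification, colocalization — plus
the matching expression-side statistics (QC filters, a rank-based
partial-EMT signature score, marker-gene rules, group-fraction tests), and a
synthetic-data generator that provides ground truth for every stage.

## Registration model

Serial sections of one block show the same tissue architecture under
section-specific smooth distortion (stretching and slight rotation from
cutting and mounting). The pipeline follows the standard skeleton:

1. every slide is downsampled so its longest side is at most 500 px
   (aspect preserved, antialiased; slides already smaller are not upsampled);
2. each non-reference slide is registered onto the reference slide — by
   default the *centroid* slide, i.e. the middle of the stack (lower index on
   ties), which minimizes the distortion any one section must bridge;
3. the recovered deformation field is upsampled to the original resolution
   (grid resampled bilinearly *and* displacement magnitudes multiplied by the
   scale ratio) and used to warp the full-resolution scan.

Registration itself is intensity-based on the *absorbance* image
(1 − grayscale/255), not raw RGB, so that marker-dependent stain color
cannot drive the alignment. It has two stages:

* a multi-resolution similarity-transform search (rotation about the image
  center, uniform scale, translation; Nelder–Mead on a mean-squared-error
  metric, with mutual information available via `config$metric = "mi"`),
  initialized from the tissue-mask centroid offset;
* demons-style dense nonrigid refinement, coarse-to-fine over a 4×/2×/1×
  pyramid, with a symmetric intensity-gradient force, a 1 px per-iteration
  step cap, and Gaussian regularization (σ = 3 px) of the total field after
  every update.

Fields use the pull-back convention throughout: `disp[r, c, ]` is the
`(d_row, d_col)` offset added to a reference-frame coordinate to find the
corresponding moving-frame coordinate; coordinates are 0-based `(row, col)`.
This convention (and the rule that upsampling scales both grid and
magnitudes) is stated explicitly because nothing about a deformation field
is testable until it is.

Registration is deterministic — there is no seeded randomness anywhere in
the optimizer — and guarded: the tissue-mask Dice coefficient is computed
before registration, after the affine stage and after the nonrigid stage;
if the nonrigid field degrades Dice the affine field is kept, and if even
that is worse than no registration the zero field is returned with a report
flag rather than silently returning a worse-than-identity result. Hard
failures (no tissue, no overlap, non-finite metric) raise a
`registration_failure` condition carrying diagnostics.

## Stain model and positive-cell detection

Brightfield IHC color is modeled with the Beer–Lambert law: per-channel
optical density `OD = −log10(I/255)` is a nonnegative linear combination of
a hematoxylin vector and a DAB vector (Ruifrok–Johnston values). The
synthetic renderer composes images in exactly this space, so deconvolution —
least-squares projection of the OD triple onto the two stain vectors,
clipped at zero — inverts it up to 8-bit quantization (worst-case OD error
about 0.05 at the densities used). How "marker-positive" was called is a
judgment the pipeline must make explicit: the default rule is DAB OD ≥ 0.15,
with positive *objects* (cells) as 8-connected components of at least 20 px
and centroids as unweighted pixel means. Both the pixel-area and the
object-count readings of "density" are provided, because compartment-level
claims are naturally about positive *area* fractions while cell-level claims
are about *counts*; pixel fraction is the default for area claims, object
count for conservation-style claims. Threshold and minimum area are
configurable; the synthetic ground truth validates the defaults rather than
tuning them per slide.

## Tiles, hotspots, colocalization

Annotated regions are dissected into non-overlapping 1000 × 1000 px tiles
(half-open intervals, 0-based, anchored at the region bounding-box origin so
the grid is invariant to joint translation of annotation and detections).
Tiles with less than 5% region-and-tissue coverage are invalid and excluded.
Per-tile density is either positive-pixel fraction (per tissue pixel) or
object count (which sums exactly to the number of objects in the gridded
region — a conservation property the tests assert exactly).

*Hotspots.* Visual reading of "the high tiles on the heatmap" is replaced by
a reproducible rule: tiles strictly above the 0.9 quantile of valid-tile
densities; when no tile exceeds that quantile (a constant map), the tiles
attaining the maximum are returned. Strict exceedance is deliberate: with a
single nonzero tile among many zeros the 0.9 quantile *is* zero, and a
"≥ quantile" rule would absurdly flag every tile. The rule is invariant to
any strictly increasing rescaling of densities.

*Colocalization.* Two markers' spatial co-occurrence is measured as the
Spearman rank correlation of their densities over jointly valid tiles, with
a two-sided permutation p-value from seeded random shuffles of one map's
tile labels, `p = (1 + #{|ρ*| ≥ |ρ|}) / (n_perm + 1)`. A rank statistic is
used because tile densities are heavily skewed and the two markers' scales
are not comparable; the permutation null conditions on both marginal
distributions. The permutation seed is a required, logged input so reported
p-values are reproducible.

## Expression statistics

* **QC filter** — cells with fewer than 400 expressed genes (value > 0) are
  dropped, then genes expressed in fewer than 4 of the remaining cells. The
  order (cells, then genes, one pass, no iteration to a fixed point) is
  fixed and recorded in the result, since the two rules do not commute.
* **p-EMT score** — per cell, all genes are ranked by expression within the
  cell (ascending, average ranks on ties) and the score is the mean rank of
  the signature genes divided by the number of ranked genes, so scores lie
  in [0, 1], higher expression means a higher score, and any strictly
  increasing per-cell transformation of the data leaves scores unchanged.
  "Mean expression rank" admits a second reading — ranking cells within each
  gene — which is exposed as `method = "cell_rank"`; the within-cell reading
  is the default because it makes scores comparable across cells with
  different library depths. The 97-gene p-EMT list is supplied by the user
  as a plain text file (one gene per line); signature genes absent from the
  matrix are excluded and counted in `n_signature_used`.
* **Group comparison** — two-sided Wilcoxon rank-sum on per-cell scores;
  exact for small untied samples, normal approximation with tie correction
  otherwise.
* **Marker genes** — per gene, two-sided Wilcoxon of target cluster versus
  all other cells; Bonferroni correction over the genes actually tested
  (constant genes are untestable and excluded from the denominator); markers
  are genes with corrected p < 0.05 *and* mean expression in the target more
  than 2-fold its mean elsewhere. A pseudocount of 1e-9 in the denominator
  handles an all-zero "rest"; fold change is computed on raw means because
  the rule is stated on expression levels, not logs.
* **Fraction tests** — per-sample cell fractions are compared with a
  normality gate mirroring common GraphPad practice: Shapiro–Wilk (α = 0.05)
  on each group (or on paired differences) and an F-test of equal variances;
  pass → t test (pooled-variance unpaired, or paired), fail → Mann–Whitney
  (or Wilcoxon signed-rank). Degenerate inputs (constant groups,
  zero-variance differences) fail the gate by definition and take the rank
  branch, with the gate outcome recorded in the result.

## What the synthetic generator emulates — and what it does not

The generator produces: one tissue layout per block (wobbly elliptical
tissue mask, disk-like tumor glands with invasive-front bands, distal
stroma, optionally a lymphoid-nodule disk), per-marker point processes that
are Poisson with constant intensity within each compartment (optionally
modulated by a shared smooth log-Gaussian field to plant tile-level
cross-marker correlation; the modulation is mean-preserving so expected
counts stay `rate × area`), Beer–Lambert renderings with a hematoxylin
texture that belongs to the *block* (shared across serial sections, as real
architecture is) plus small per-section staining noise, and per-section
smooth random deformations (white noise blurred at a stated length scale,
rescaled so the maximum displacement is exactly `max_disp`, plus an optional
rigid part) with landmark pairs that satisfy `fixed = moving + disp[moving]`
exactly. Expression matrices are log-normal with Bernoulli dropout and a
multiplicative boost `1 + effect` on signature genes in the elevated group,
so `effect = 0` is the exact null and the expected score shift is monotone
in `effect`.

Not emulated: nuclear texture, scanner artifacts, stain variation between
scanners, tearing/folding (non-smooth deformation), multiplexed staining,
and realistic single-cell count distributions. Passing tests therefore show
that the *algorithms* recover known truth under smooth distortion and
Poisson sampling; they do not certify performance on slides whose artifacts
violate those assumptions.

## Numerical choices and degenerate inputs

* Bilinear interpolation everywhere; out-of-canvas samples are white for
  slides, a caller-chosen fill for matrices, and nearest-edge clamped for
  field resampling and field inversion (a field has no natural "background").
* Field inversion is the standard fixed-point iteration
  `G ← −D(x + G(x))`, stopped at a 1e-3 px update.
* The study-scale problem sizes used by the test suite and the acceptance
  script — three 2000 × 2000 sections registered at a 500 px working scale,
  a maximum true displacement of 15 px at that scale (60 px at full
  resolution), 500 simulated grids for permutation-test calibration, 20
  gradient replicates and 8 synthetic patients — are the package's reference
  study conditions; they were chosen to represent desk-scale whole-slide
  crops while keeping every check runnable on one CPU.
* The paired-comparison check plants a compartment-fraction difference of
  about 2 patient-level standard deviations — comfortably inside the
  "at least 1 SD" regime it is meant to demonstrate — because a single
  paired test at n = 8 near 1 SD has appreciable type-II error by design,
  which would make a deterministic check dishonest.
* Gland packing uses rejection sampling with periodic restarts; infeasible
  requests (too many glands for the canvas) raise a sizing error rather
  than degrading the geometry.
* A deformation that would carry tissue off the canvas (more than 0.5% of
  tissue pixels without a preimage) is rejected with a bounds error; the
  check splats forward-mapped coordinates and dilates by one pixel to
  absorb rounding gaps, so legitimate local expansion is not flagged.

## Known limitations

* The nonrigid stage recovers smooth fields to ~2–3 px at the working scale
  under the reference conditions; high-frequency deformation below the
  texture correlation length is unrecoverable in principle.
* Slides are processed in memory as dense arrays; gigapixel WSIs would need
  tiled streaming, which is out of scope.
* The colocalization statistic is tile-level, not point-level; cell-pair
  neighborhood analyses (cross-PCF, Ripley's K) are deliberately not
  implemented.
* Spatial autocorrelation of tile densities makes the permutation null
  slightly liberal in principle; at the planted smoothness and tile sizes
  used here the calibration check keeps the empirical size within 5% ± 3%.
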