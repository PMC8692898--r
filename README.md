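# serialihc

Spatial analysis of serially sectioned, single-marker IHC slides of
gastric-cancer tissue, plus the matching single-cell expression statistics.

Conventional immunohistochemistry stains one marker per slide, so the
spatial relationships between markers — where POSTN-high eCAFs sit relative
to CD163+ M2 macrophages, whether exhausted T cells share lymphoid
structures with iCAFs — can only be read by aligning consecutive serial
sections into one coordinate frame. `serialihc` implements that pipeline for
desk-scale whole-slide crops:

* **Registration** — slides are downsampled to a ≤ 500 px working scale,
  registered onto the *centroid* (middle) slide by a multi-resolution
  similarity transform followed by demons-style nonrigid refinement on
  absorbance (so stain color never drives alignment); the deformation field
  is upsampled (grid **and** magnitudes) to full resolution and used to warp
  the original scans. Fields are pull-back displacements in 0-based
  `(row, col)` pixels.
* **Stain quantification** — Beer–Lambert hematoxylin/DAB deconvolution
  (Ruifrok–Johnston vectors), marker-positive masks at a DAB
  optical-density threshold (default 0.15), 8-connected positive objects
  (default ≥ 20 px), and positive-area fractions per annotated compartment
  (tumor gland **T**, invasive front **IF**, distal stroma **S**, lymphoid
  nodule **LN**).
* **Tile statistics** — annotated regions dissected into 1000 × 1000 px
  tiles; per-tile densities (pixel fraction or object count), heatmaps with
  exact CSV twins, top-decile hotspot calls, and cross-marker
  colocalization as tile-wise Spearman ρ with a seeded permutation p-value.
* **Expression statistics** — the ≥ 400 genes/cell, ≥ 4 cells/gene QC
  filter; the p-EMT signature score (per-cell mean expression rank of the
  ~97-gene list, normalized to [0, 1]) with Wilcoxon rank-sum group
  comparison; the Wilcoxon + Bonferroni < 0.05 + > 2-fold marker-gene rule;
  and normality-gated group-fraction tests (Shapiro–Wilk/F-test gate →
  t test or Mann–Whitney / signed-rank).
* **Synthetic ground truth** — generators for tissue layouts, planted
  Poisson marker point processes (with optional latent-field colocalization),
  Beer–Lambert slide renderings, smooth known deformations with exact
  landmark pairs, and expression matrices with planted signature effects.
  Every algorithmic claim in the package is tested against these.

## Worked example

```r
library(serialihc)

# 1. simulate a two-marker serial study (one 1000 x 1000 block)
study <- simulate_serial_study(width = 1000, height = 1000, n_glands = 2,
                               rates = list(POSTN = c(T = 5e-5, IF = 3e-4, S = 6e-4),
                                            CD163 = c(T = 1e-4, IF = 3e-4, S = 4e-4)),
                               max_disp = 30, smoothness = 150,
                               coloc_rho = 0.7, seed = 7)

# 2. register the stack onto the centroid slide and warp into one frame
reg <- register_stack(study$images, reference = "centroid")
reg$reports[[2]]
#> <registration_report> affine+demons: Dice 0.9680 -> 0.9951, final metric 0.00357
landmark_tre(reg$fields[[2]], study$ground_truth[[2]]$landmarks)
#> [1] 5.042834      # mean landmark error, full-resolution px (2.5 px at working scale)

aligned <- lapply(seq_along(study$images),
                  function(i) warp(study$images[[i]], reg$fields[[i]]))

# 3. stain separation and positive detection per marker
dets <- lapply(aligned, function(im) detect_positive(deconvolve_hdab(im)))
names(dets) <- vapply(study$images, `[[`, "", "marker")
dets$POSTN
#> <positive_detection> 24703 positive px (2.47%), 222 objects (OD >= 0.15, area >= 20)

# 4. compartment profile and tile-level colocalization
compartment_profile(dets, study$layout)
#>   marker compartment section    fraction
#> 1  POSTN           T       1 0.006747425
#> 2  POSTN          IF       1 0.028381179
#> 3  POSTN           S       1 0.057370514
#> 4  CD163           T       1 0.003077773
#> 5  CD163          IF       1 0.022500868
#> 6  CD163           S       1 0.033115214

grid <- tile_region(study$layout$tissue_mask, study$layout$tissue_mask,
                    tile_size = 100)
maps <- lapply(names(dets), function(mk)
  density_map(dets[[mk]], grid, mode = "pixel_fraction", marker = mk))
colocalize(maps[[1]], maps[[2]], n_perm = 1000, seed = 99)
#> <coloc_result> POSTN vs CD163: Spearman rho = 0.534, perm p = 0.000999 (67 tiles, 1000 perms, seed 99)

# 5. expression side: planted p-EMT shift between tumor and normal cells
sig <- sprintf("gene%d", 1:97)
expr <- simulate_expression(400, 2000, signature = sig,
                            group_labels = rep(c("normal", "tumor"), each = 200),
                            effect = 4, seed = 1)
expr <- qc_filter(expr, min_genes_per_cell = 400, min_cells_per_gene = 4)
sc <- pemt_score(expr, sig)
compare_scores(sc, expr$cell_data$group)
#> <test_result> wilcoxon_rank_sum: statistic = 6273, p = 1.642e-32 (n = 200/200)
```

Reading the numbers: registration lifts the tissue-overlap Dice from 0.968
to 0.995 and localizes planted landmarks to ~2.5 px at the 500 px working
scale; the planted stromal POSTN gradient (S > IF > T) appears directly in
the compartment fractions; the planted latent-field coupling between POSTN
and CD163 shows up as tile-wise ρ = 0.53 with a permutation p below 0.001;
and the planted signature boost separates tumor from normal scores
decisively.

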