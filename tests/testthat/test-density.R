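test_that("tiling anchors at the region bounding box and tracks tissue area", {
  tissue <- matrix(TRUE, 300, 220)
  region <- matrix(FALSE, 300, 220); region[1:300, 1:200] <- TRUE
  g <- tile_region(region, tissue, tile_size = 100, min_tissue = 0.05)
  expect_identical(c(g$n_rows, g$n_cols), c(3L, 2L))
  expect_identical(g$origin, c(0, 0))
  expect_true(all(g$tissue_px == 1e4))
  expect_true(all(g$valid))
  # offset region anchors at its own bounding box, not the slide origin
  region2 <- matrix(FALSE, 300, 220); region2[51:150, 61:160] <- TRUE
  g2 <- tile_region(region2, tissue, tile_size = 100)
  expect_identical(g2$origin, c(50, 60))
  expect_identical(c(g2$n_rows, g2$n_cols), c(1L, 1L))
  # degenerate 1-px region: one tile, invalid under min_tissue
  region3 <- matrix(FALSE, 300, 220); region3[10, 10] <- TRUE
  g3 <- tile_region(region3, tissue, tile_size = 100, min_tissue = 0.05)
  expect_identical(c(g3$n_rows, g3$n_cols), c(1L, 1L))
  expect_false(any(g3$valid))
  # circular region: boundary tiles valid iff tissue fraction >= min_tissue
  circ <- draw_blobs(300, 220, matrix(c(150, 110), 1), radius = 80) > 0
  g4 <- tile_region(circ, tissue, tile_size = 50, min_tissue = 0.05)
  expect_identical(g4$valid, g4$tissue_px >= 0.05 * 50^2)
  expect_true(any(g4$valid) && !all(g4$valid))
  expect_error(tile_region(region, matrix(FALSE, 300, 220)), "intersect")
})

test_that("object-count densities conserve the planted total and use half-open tiles", {
  tissue <- matrix(TRUE, 200, 200)
  region <- tissue
  g <- tile_region(region, tissue, tile_size = 100)
  # 7 objects in one tile
  obj <- data.frame(row = c(10, 20, 30, 40, 50, 60, 70), col = rep(25, 7),
                    area = rep(30L, 7))
  det <- make_detection(matrix(FALSE, 200, 200), objects = obj)
  m <- density_map(det, g, mode = "object_count")
  expect_equal(m$values[1, 1], 7)
  expect_equal(sum(m$values), 7)
  # centroid exactly on a shared edge goes to the lower-right neighbour
  det2 <- make_detection(matrix(FALSE, 200, 200),
                         objects = data.frame(row = 100, col = 100, area = 30L))
  m2 <- density_map(det2, g, mode = "object_count")
  expect_equal(m2$values[2, 2], 1)
  expect_equal(sum(m2$values), 1)
})

test_that("uniform planted positives give near-uniform pixel fractions", {
  lay <- fix_layout()
  pts <- plant_marker_points(lay, list(M = c(T = 2e-3, IF = 2e-3, S = 2e-3)),
                             seed = 31)$M
  dab <- draw_blobs(lay$height, lay$width, pts$points, radius = 3) * 0.8
  det <- detect_positive(make_channels(dab), threshold = 0.15, min_area = 3)
  g <- tile_region(lay$tissue_mask, lay$tissue_mask, tile_size = 60,
                   min_tissue = 0.5)
  m <- density_map(det, g, mode = "pixel_fraction")
  v <- m$values[m$grid$valid]
  p <- sum(det$mask & lay$tissue_mask) / sum(lay$tissue_mask)
  # per-tile fractions scatter around the global fraction
  expect_lt(abs(mean(v) - p), 3 * sd(v) / sqrt(length(v)))
})

test_that("hotspot calls follow the top-quantile rule with sensible ties", {
  # all tiles equal -> all are hotspots
  hs <- hotspots(make_map(matrix(2, 5, 5)), quantile = 0.9)
  expect_identical(nrow(hs), 25L)
  # one nonzero tile among 100 -> exactly that tile
  v <- matrix(0, 10, 10); v[4, 7] <- 3
  hs2 <- hotspots(make_map(v), quantile = 0.9)
  expect_identical(nrow(hs2), 1L)
  expect_identical(c(hs2$tile_row, hs2$tile_col), c(3L, 6L))
  # planted two-cluster map: hotspot set equals the planted high tiles
  v3 <- matrix(rep(c(1, 1, 1, 1, 9), 5), 5, 5)
  hs3 <- hotspots(make_map(v3), quantile = 0.75)
  expect_identical(sort(hs3$tile_row), rep(4L, 5))
  # invariance under monotone rescaling
  set.seed(8)
  v4 <- matrix(runif(100), 10, 10)
  h_raw <- hotspots(make_map(v4))
  h_tr <- hotspots(make_map(exp(3 * v4) + 7))
  expect_identical(h_raw[c("tile_row", "tile_col")], h_tr[c("tile_row", "tile_col")])
})

test_that("colocalization statistic and permutation p behave at the extremes", {
  set.seed(9)
  v <- matrix(rgamma(64, 2), 8, 8)
  a <- make_map(v, marker = "POSTN")
  b <- make_map(v + 0.001 * v^2, marker = "CD163")   # monotone of a
  cl <- colocalize(a, b, n_perm = 500, seed = 3)
  expect_equal(cl$statistic, 1)
  expect_lt(cl$p_perm, 0.01)
  expect_identical(cl$n_tiles, 64L)
  # seeded: same call, same p
  cl2 <- colocalize(a, b, n_perm = 500, seed = 3)
  expect_identical(cl$p_perm, cl2$p_perm)
  # constant map -> undefined statistic
  expect_error(colocalize(make_map(matrix(1, 8, 8)), a), "constant")
})

test_that("heatmap rendering writes an exact CSV twin and a monotone colormap", {
  v <- matrix(seq(0, 1, length.out = 6), 1, 6)
  v[1, 3] <- NA   # invalid tile
  m <- make_map(v)
  m$grid$valid[1, 3] <- FALSE
  out <- file.path(tempdir(), "hm.png")
  paths <- render_heatmap(m, out, cell_px = 4)
  df <- read_heatmap_csv(paths$csv)
  expect_equal(df$density[order(df$tile_col)], as.numeric(v))
  img <- png::readPNG(paths$png)
  expect_identical(dim(img)[1:2], c(4L, 24L))
  # viridis luminance rises with density
  lum <- sapply(c(1, 2, 4, 5, 6), function(j) mean(img[1:4, (j - 1) * 4 + 1:4, ]))
  expect_true(all(diff(lum) > 0))
})

test_that("compartment profiles recover planted spatial structure", {
  lay <- fix_layout()
  masks <- compartment_masks(lay)
  # marker planted only in S -> zero fraction in T and IF by construction
  pts <- plant_marker_points(lay, list(M = c(S = 1.5e-3)), seed = 41)$M
  blobs <- draw_blobs(lay$height, lay$width, pts$points, radius = 3) > 0
  det <- make_detection(blobs & masks$S)
  prof <- compartment_profile(list(M = det), lay)
  expect_equal(prof$fraction[prof$compartment == "T"], 0)
  expect_equal(prof$fraction[prof$compartment == "IF"], 0)
  expect_gt(prof$fraction[prof$compartment == "S"], 0)
  # planted S > IF > T gradient is recovered
  pts2 <- plant_marker_points(lay, list(M = c(T = 1e-4, IF = 8e-4, S = 2.5e-3)),
                              seed = 42)$M
  dab <- draw_blobs(lay$height, lay$width, pts2$points, radius = 3) * 0.8
  det2 <- detect_positive(make_channels(dab), threshold = 0.15, min_area = 3)
  p2 <- compartment_profile(list(M = det2), lay)
  f <- setNames(p2$fraction, p2$compartment)
  expect_true(f["S"] > f["IF"] && f["IF"] > f["T"])
  # two sections with the same planting agree within sampling noise
  reps <- vapply(1:2, function(k) {
    pp <- plant_marker_points(lay, list(M = c(S = 2e-3)), seed = 50 + k)$M
    dd <- draw_blobs(lay$height, lay$width, pp$points, radius = 3) * 0.8
    det_k <- detect_positive(make_channels(dd), threshold = 0.15, min_area = 3)
    positive_area_fraction(det_k, masks$S, lay$tissue_mask)
  }, numeric(1))
  n_expected <- 2e-3 * sum(masks$S)
  expect_lt(abs(reps[1] - reps[2]) / mean(reps), 6 / sqrt(n_expected))
  # a compartment absent from the annotation is omitted with a warning
  expect_warning(compartment_profile(list(M = det), lay,
                                     compartments = c("T", "XX")),
                 "omitted")
})
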