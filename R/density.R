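#' Tile an annotated region into fixed-size blocks
#'
#' The region is dissected into non-overlapping `tile_size` x `tile_size`
#' pixel tiles (half-open intervals, 0-based), anchored at the top-left of
#' the region's bounding box. Tiles whose region-and-tissue coverage is below
#' `min_tissue` of the tile area are marked invalid and excluded from density
#' statistics.
#'
#' @param region polygon (ring matrix or `list(outer=, holes=)`) or logical
#'   mask in slide coordinates.
#' @param tissue logical tissue mask, same frame.
#' @param tile_size tile side in pixels (the conventional block is 1000).
#' @param min_tissue minimum tissue fraction of a tile's area to be valid.
#' @return A `tile_grid`: `origin` (0-based `(row, col)`), `tile_size`,
#'   `n_rows`, `n_cols`, `tissue_px` (matrix), `valid` (matrix), and the
#'   rasterized `region_mask`.
#' @export
tile_region <- function(region, tissue, tile_size = 1000, min_tissue = 0.05) {
  stopifnot(is.logical(tissue), tile_size >= 1)
  rmask <- as_region_mask(region, nrow(tissue), ncol(tissue))
  cov <- rmask & tissue
  if (!any(cov)) stop("region does not intersect tissue", call. = FALSE)
  idx <- which(rmask)
  h <- nrow(tissue)
  rows <- (idx - 1) %% h; cols <- (idx - 1) %/% h
  origin <- c(min(rows), min(cols))
  n_rows <- ceiling((max(rows) - origin[1] + 1) / tile_size)
  n_cols <- ceiling((max(cols) - origin[2] + 1) / tile_size)
  cidx <- which(cov)
  tr <- ((cidx - 1) %% h - origin[1]) %/% tile_size
  tc <- ((cidx - 1) %/% h - origin[2]) %/% tile_size
  tissue_px <- matrix(0, n_rows, n_cols)
  tab <- table(factor(tr, levels = 0:(n_rows - 1)), factor(tc, levels = 0:(n_cols - 1)))
  tissue_px[] <- as.numeric(tab)
  valid <- tissue_px >= min_tissue * tile_size^2
  structure(list(origin = origin, tile_size = as.integer(tile_size),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 tissue_px = tissue_px, valid = valid, region_mask = rmask),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %d px at origin (%d, %d); %d valid\n",
              x$n_rows, x$n_cols, x$tile_size, x$origin[1], x$origin[2],
              sum(x$valid)))
  invisible(x)
}

#' Per-tile marker-positive density map
#'
#' For `mode = "pixel_fraction"` each valid tile's density is its
#' marker-positive pixel count (within region and tissue) divided by its
#' tissue pixel count; for `mode = "object_count"` it is the number of
#' detected positive objects whose centroid falls inside the tile (half-open
#' tile intervals decide boundary points, so object counts sum exactly to the
#' total object count inside the gridded region). Invalid tiles carry `NA`.
#'
#' @param det a `positive_detection` in the same (registered reference) frame
#'   as the grid.
#' @param grid a `tile_grid`.
#' @param mode `"pixel_fraction"` or `"object_count"`.
#' @param marker marker name carried into the result.
#' @return A `density_map`: `marker`, `grid`, `values` (n_rows x n_cols,
#'   `NA` where invalid), `mode`.
#' @export
density_map <- function(det, grid, mode = c("pixel_fraction", "object_count"),
                        marker = "marker") {
  stopifnot(inherits(det, "positive_detection"), inherits(grid, "tile_grid"))
  mode <- match.arg(mode)
  if (!identical(dim(det$mask), dim(grid$region_mask)))
    stop("detection and grid are in different coordinate frames", call. = FALSE)
  ts <- grid$tile_size
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  if (mode == "pixel_fraction") {
    pos <- det$mask & grid$region_mask
    idx <- which(pos)
    if (length(idx)) {
      h <- nrow(det$mask)
      tr <- ((idx - 1) %% h - grid$origin[1]) %/% ts
      tc <- ((idx - 1) %/% h - grid$origin[2]) %/% ts
      ok <- tr >= 0 & tr < grid$n_rows & tc >= 0 & tc < grid$n_cols
      tab <- table(factor(tr[ok], levels = 0:(grid$n_rows - 1)),
                   factor(tc[ok], levels = 0:(grid$n_cols - 1)))
      vals[] <- as.numeric(tab)
    }
    vals <- ifelse(grid$tissue_px > 0, vals / pmax(grid$tissue_px, 1), 0)
  } else {
    if (nrow(det$objects)) {
      tr <- floor((det$objects$row - grid$origin[1]) / ts)
      tc <- floor((det$objects$col - grid$origin[2]) / ts)
      ok <- tr >= 0 & tr < grid$n_rows & tc >= 0 & tc < grid$n_cols
      tab <- table(factor(tr[ok], levels = 0:(grid$n_rows - 1)),
                   factor(tc[ok], levels = 0:(grid$n_cols - 1)))
      vals[] <- as.numeric(tab)
    }
  }
  vals[!grid$valid] <- NA_real_
  structure(list(marker = marker, grid = grid, values = vals, mode = mode),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  v <- x$values[x$grid$valid]
  cat(sprintf("<density_map> %s (%s): %d valid tiles, density %.4g-%.4g\n",
              x$marker, x$mode, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Call hotspot tiles on a density map
#'
#' Hotspots are the upper tail of the valid-tile density distribution: tiles
#' strictly above the `quantile` of valid densities; when no tile exceeds the
#' quantile (it equals the maximum, e.g. on a constant map) the tiles
#' attaining the maximum are returned, so ties at the top are always
#' included. The call is invariant to any strictly increasing rescaling of
#' the densities.
#'
#' @param map a `density_map`.
#' @param quantile tail quantile defining a hotspot (default top decile).
#' @return Data frame `tile_row`, `tile_col` (0-based), `density`.
#' @export
hotspots <- function(map, quantile = 0.9) {
  stopifnot(inherits(map, "density_map"), quantile >= 0, quantile <= 1)
  valid <- map$grid$valid
  if (!any(valid)) stop("all tiles are invalid", call. = FALSE)
  v <- map$values[valid]
  thr <- stats::quantile(v, quantile, names = FALSE)
  hot <- valid & !is.na(map$values) & map$values > thr
  if (!any(hot)) hot <- valid & !is.na(map$values) & map$values == max(v)
  idx <- which(hot)
  data.frame(tile_row = as.integer((idx - 1) %% nrow(hot)),
             tile_col = as.integer((idx - 1) %/% nrow(hot)),
             density = map$values[idx])
}

#' Tile-wise colocalization of two markers
#'
#' Spearman rank correlation of two markers' densities over jointly valid
#' tiles, with a two-sided permutation p-value from `n_perm` seeded random
#' shuffles of the second map's tile labels:
#' `p = (1 + #permutations with |rho| >= |rho_obs|) / (n_perm + 1)`.
#'
#' @param a,b `density_map`s on the same grid.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream (required, logged in
#'   the result).
#' @return A `coloc_result`: `marker_pair`, `statistic` (Spearman rho),
#'   `p_perm`, `n_tiles`, `n_perm`, `seed`.
#' @export
colocalize <- function(a, b, n_perm = 1000, seed = 1) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"), n_perm >= 1)
  if (!identical(dim(a$values), dim(b$values)) ||
      !identical(a$grid$origin, b$grid$origin) ||
      a$grid$tile_size != b$grid$tile_size)
    stop("density maps must share a tile grid", call. = FALSE)
  joint <- a$grid$valid & b$grid$valid & !is.na(a$values) & !is.na(b$values)
  if (sum(joint) < 3) stop("fewer than 3 jointly valid tiles", call. = FALSE)
  va <- a$values[joint]; vb <- b$values[joint]
  if (sd(va) == 0 || sd(vb) == 0)
    stop("constant density map: colocalization statistic undefined", call. = FALSE)
  ra <- rank(va); rb <- rank(vb)
  n <- length(ra)
  za <- (ra - mean(ra)) / sd(ra)
  zb <- (rb - mean(rb)) / sd(rb)
  rho <- sum(za * zb) / (n - 1)
  perm_rho <- with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n))          # n x n_perm
    as.numeric(crossprod(matrix(zb[idx], n, n_perm), za)) / (n - 1)
  })
  p <- (1 + sum(abs(perm_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
  structure(list(marker_pair = c(a$marker, b$marker), statistic = rho,
                 p_perm = p, n_tiles = n, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s vs %s: Spearman rho = %.3f, perm p = %.4g (%d tiles, %d perms, seed %d)\n",
              x$marker_pair[1], x$marker_pair[2], x$statistic, x$p_perm,
              x$n_tiles, x$n_perm, x$seed))
  invisible(x)
}

#' Write a density heatmap image and its CSV twin
#'
#' Renders one PNG cell per tile (scaled up by `cell_px`) with a perceptually
#' monotone colormap (viridis); invalid tiles are drawn gray. A CSV twin
#' holding the exact per-tile values (`tile_row`, `tile_col`, `density`,
#' `tissue_px`, `valid`) is written next to the image, full precision, so
#' re-reading it reproduces the map values bit for bit.
#'
#' @param map a `density_map`.
#' @param out PNG output path; the CSV twin replaces the extension with
#'   `.csv`.
#' @param cell_px rendered pixels per tile.
#' @return Invisibly, a list with the written `png` and `csv` paths.
#' @export
render_heatmap <- function(map, out, cell_px = 8) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  rng <- range(v, na.rm = TRUE)
  u <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255
  ii <- pmin(pmax(round(u * 255) + 1, 1), 256)
  h <- nrow(v); w <- ncol(v)
  img <- array(0.5, c(h, w, 3))           # gray for invalid
  ok <- !is.na(v)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ok] <- pal[ch, ii[ok]]
    img[, , ch] <- plane
  }
  big <- array(0, c(h * cell_px, w * cell_px, 3))
  rep_r <- rep(seq_len(h), each = cell_px)
  rep_c <- rep(seq_len(w), each = cell_px)
  for (ch in 1:3) big[, , ch] <- img[rep_r, rep_c, ch]
  png::writePNG(big, out)
  csv <- sub("\\.[a-zA-Z]+$", ".csv", out)
  idx <- which(matrix(TRUE, h, w))
  df <- data.frame(tile_row = (idx - 1) %% h,
                   tile_col = (idx - 1) %/% h,
                   density = format(v[idx], digits = 17, scientific = TRUE, trim = TRUE),
                   tissue_px = map$grid$tissue_px[idx],
                   valid = map$grid$valid[idx])
  write.csv(df, csv, row.names = FALSE, quote = FALSE)
  invisible(list(png = out, csv = csv))
}

#' Read back the CSV twin of a density heatmap
#'
#' @param csv path written by [render_heatmap()].
#' @return Data frame with numeric `density` (`NA` for invalid tiles).
#' @export
read_heatmap_csv <- function(csv) {
  df <- read.csv(csv)
  df$density <- as.numeric(df$density)
  df
}

#' Per-compartment positive-area fractions across markers and sections
#'
#' For each marker's detection (already registered into the reference frame)
#' and each annotated compartment, computes the marker-positive area fraction
#' via [positive_area_fraction()]. Compartments absent from the annotation
#' are omitted with a warning. The resulting long table feeds the
#' compartment-level group tests (e.g. paired comparisons across patients).
#'
#' @param detections named list (by marker) of `positive_detection`s, or a
#'   list of such lists (one per section).
#' @param annotation a `tissue_layout` (compartment polygons + tissue mask in
#'   reference coordinates).
#' @param compartments compartment labels to profile.
#' @param section section index (used when `detections` is a single
#'   marker-keyed list).
#' @return Data frame `marker`, `compartment`, `section`, `fraction`.
#' @export
compartment_profile <- function(detections, annotation,
                                compartments = c("T", "IF", "S"), section = 1L) {
  stopifnot(inherits(annotation, "tissue_layout"))
  per_section <- if (inherits(detections[[1]], "positive_detection"))
    list(detections) else detections
  masks <- compartment_masks(annotation)
  missing <- setdiff(compartments, names(masks))
  if (length(missing)) {
    warning("compartment(s) missing from annotation, omitted: ",
            paste(missing, collapse = ", "))
    compartments <- setdiff(compartments, missing)
  }
  rows <- list()
  for (s in seq_along(per_section)) {
    dets <- per_section[[s]]
    for (mk in names(dets)) {
      for (cp in compartments) {
        rows[[length(rows) + 1]] <- data.frame(
          marker = mk, compartment = cp,
          section = if (length(per_section) > 1) s else section,
          fraction = positive_area_fraction(dets[[mk]], masks[[cp]],
                                            annotation$tissue_mask))
      }
    }
  }
  do.call(rbind, rows)
}
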