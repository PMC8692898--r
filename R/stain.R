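#' Hematoxylin / DAB stain vectors
#'
#' Unit optical-density RGB vectors for hematoxylin and DAB
#' (Ruifrok-Johnston values), used both by the synthetic renderer
#' (composition) and by [deconvolve_hdab()] (unmixing), so the pair is an
#' exact inverse up to 8-bit quantization.
#'
#' @return 2 x 3 matrix, rows `hema` and `dab`, each a unit vector.
#' @export
hdab_stain_vectors <- function() {
  v <- rbind(hema = c(0.650, 0.704, 0.286),
             dab = c(0.269, 0.568, 0.776))
  v / sqrt(rowSums(v^2))
}

#' Separate hematoxylin and DAB optical densities
#'
#' Per-pixel Beer-Lambert optical density `OD = -log10(I / 255)` is computed
#' for each RGB channel and projected onto the stain vectors by least squares,
#' giving per-stain concentration maps (clipped at 0).
#'
#' @param image a [slide_image()] or H x W x 3 array of 8-bit RGB.
#' @param stain_vectors optional 2 x 3 matrix of stain OD vectors; defaults to
#'   [hdab_stain_vectors()].
#' @return A `stain_channels` object: `hema_od` and `dab_od` (H x W float
#'   matrices) and `stain_vectors`.
#' @export
deconvolve_hdab <- function(image, stain_vectors = NULL) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  stopifnot(is.array(px), length(dim(px)) == 3, dim(px)[3] == 3)
  if (is.null(stain_vectors)) stain_vectors <- hdab_stain_vectors()
  stopifnot(is.matrix(stain_vectors), nrow(stain_vectors) == 2, ncol(stain_vectors) == 3)
  g <- stain_vectors %*% t(stain_vectors)
  if (abs(det(g)) < 1e-8) stop("stain vectors are singular (linearly dependent)", call. = FALSE)
  pinv <- solve(g, stain_vectors)          # 2 x 3, least-squares projector
  h <- dim(px)[1]; w <- dim(px)[2]
  od <- -log10(pmax(px, 1) / 255)
  odm <- matrix(od, h * w, 3)
  conc <- odm %*% t(pinv)
  conc[conc < 0] <- 0
  structure(list(hema_od = matrix(conc[, 1], h, w),
                 dab_od = matrix(conc[, 2], h, w),
                 stain_vectors = stain_vectors),
            class = "stain_channels")
}

#' @export
print.stain_channels <- function(x, ...) {
  cat(sprintf("<stain_channels> %d x %d; hema OD max %.2f, DAB OD max %.2f\n",
              nrow(x$dab_od), ncol(x$dab_od), max(x$hema_od), max(x$dab_od)))
  invisible(x)
}

#' Detect marker-positive signal on the DAB channel
#'
#' Marker-positive pixels are those with DAB optical density at or above
#' `threshold`; positive objects (cells) are 8-connected components of the
#' mask with at least `min_area` pixels, reported with their unweighted
#' centroid in 0-based `(row, col)` coordinates.
#'
#' @param channels a `stain_channels` from [deconvolve_hdab()].
#' @param threshold OD threshold for positivity.
#' @param min_area minimum object area in pixels.
#' @return A `positive_detection`: `mask` (logical H x W), `objects`
#'   (data frame `row`, `col`, `area`), `threshold`, `min_area`.
#' @export
detect_positive <- function(channels, threshold = 0.15, min_area = 20) {
  stopifnot(inherits(channels, "stain_channels"), is.finite(threshold), min_area >= 1)
  if (!all(is.finite(channels$dab_od))) stop("DAB channel must be finite", call. = FALSE)
  mask <- channels$dab_od >= threshold
  objects <- data.frame(row = numeric(0), col = numeric(0), area = integer(0))
  if (any(mask)) {
    lab <- label_components8(mask)
    idx <- which(lab > 0)
    ids <- lab[idx]
    h <- nrow(mask)
    rows <- (idx - 1) %% h
    cols <- (idx - 1) %/% h
    area <- as.integer(tapply(rep(1L, length(ids)), ids, sum))
    keep <- which(area >= min_area)
    if (length(keep)) {
      objects <- data.frame(
        row = as.numeric(tapply(rows, ids, mean))[keep],
        col = as.numeric(tapply(cols, ids, mean))[keep],
        area = area[keep])
      rownames(objects) <- NULL
    }
  }
  structure(list(mask = mask, objects = objects, threshold = threshold,
                 min_area = min_area),
            class = "positive_detection")
}

#' @export
print.positive_detection <- function(x, ...) {
  cat(sprintf("<positive_detection> %d positive px (%.2f%%), %d objects (OD >= %.2f, area >= %d)\n",
              sum(x$mask), 100 * mean(x$mask), nrow(x$objects), x$threshold, x$min_area))
  invisible(x)
}

#' Marker-positive area fraction within a region
#'
#' The fraction of region-and-tissue pixels that are marker positive:
#' `|positive n region n tissue| / |region n tissue|`.
#'
#' @param det a `positive_detection`.
#' @param region a polygon (`list(outer=, holes=)` or ring matrix of 0-based
#'   `(row, col)` vertices) or a logical mask.
#' @param tissue logical tissue mask in the same frame.
#' @return Fraction in \[0, 1\].
#' @export
positive_area_fraction <- function(det, region, tissue) {
  stopifnot(inherits(det, "positive_detection"), is.logical(tissue))
  rmask <- as_region_mask(region, nrow(tissue), ncol(tissue))
  denom <- rmask & tissue
  if (!any(denom)) stop("region does not intersect tissue: fraction undefined", call. = FALSE)
  sum(det$mask & denom) / sum(denom)
}
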