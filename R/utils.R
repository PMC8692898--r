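#' @import stats
#' @import utils
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generators in the package route their
# randomness through this so no call touches global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Bilinear sampling of matrix `m` at continuous 0-based (r, c) positions.
# Out-of-canvas samples return `fill`; with fill = NA coordinates are clamped
# to the canvas (nearest-edge extension), which is what field resampling and
# field inversion want.
bilinear_sample <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;   fc <- c - c0
  inside <- r >= 0 & c >= 0 & r <= nr - 1 & c <= nc - 1
  # clamp so index arithmetic stays legal; outside values overwritten below
  r0c <- pmin(pmax(r0, 0), nr - 1); c0c <- pmin(pmax(c0, 0), nc - 1)
  r1c <- pmin(r0c + 1, nr - 1);     c1c <- pmin(c0c + 1, nc - 1)
  frc <- ifelse(r0 < 0, 0, ifelse(r0 >= nr - 1, 0, fr))
  fcc <- ifelse(c0 < 0, 0, ifelse(c0 >= nc - 1, 0, fc))
  i00 <- r0c + 1 + nr * c0c
  i10 <- r1c + 1 + nr * c0c
  i01 <- r0c + 1 + nr * c1c
  i11 <- r1c + 1 + nr * c1c
  v <- (1 - frc) * (1 - fcc) * m[i00] + frc * (1 - fcc) * m[i10] +
    (1 - frc) * fcc * m[i01] + frc * fcc * m[i11]
  if (!is.na(fill)) v[!inside] <- fill
  v
}

# Gaussian smoothing of a plain matrix; thin wrapper so kernel-size edge cases
# (sigma large relative to the matrix) degrade gracefully.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  # gblur's kernel is 2*ceiling(3*sigma)+1 wide and must fit inside the image
  max_sigma <- (min(dim(m)) - 1) / 6.5
  as.matrix(EBImage::gblur(m, sigma = min(sigma, max_sigma)))
}

# Dice coefficient 2|A n B| / (|A| + |B|) of two logical masks.
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# Rasterize one polygon ring (n x 2 matrix of 0-based (row, col) vertices)
# into an H x W logical mask using even-odd pixel-center crossing counts.
rasterize_ring <- function(ring, height, width) {
  stopifnot(is.matrix(ring), ncol(ring) == 2, nrow(ring) >= 3)
  rmin <- max(0L, floor(min(ring[, 1])));  rmax <- min(height - 1L, ceiling(max(ring[, 1])))
  cmin <- max(0L, floor(min(ring[, 2])));  cmax <- min(width - 1L, ceiling(max(ring[, 2])))
  out <- matrix(FALSE, height, width)
  if (rmax < rmin || cmax < cmin) return(out)
  rr <- rmin:rmax; cc <- cmin:cmax
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  cross <- matrix(0L, length(rr), length(cc))
  v <- rbind(ring, ring[1, , drop = FALSE])
  for (k in seq_len(nrow(ring))) {
    y1 <- v[k, 1]; x1 <- v[k, 2]; y2 <- v[k + 1, 1]; x2 <- v[k + 1, 2]
    if (y1 == y2) next
    hit <- ((y1 > R) != (y2 > R))
    xint <- x1 + (R - y1) * (x2 - x1) / (y2 - y1)
    cross <- cross + (hit & (C < xint))
  }
  out[rr + 1, cc + 1] <- (cross %% 2L) == 1L
  out
}

# Rasterize a polygon given as list(outer = ring, holes = list(rings)).
rasterize_polygon <- function(poly, height, width) {
  m <- rasterize_ring(poly$outer, height, width)
  for (h in poly$holes) m <- m & !rasterize_ring(h, height, width)
  m
}

# Accepts a polygon (list with $outer), a bare ring matrix, or a logical mask
# and returns a logical mask of the stated size.
as_region_mask <- function(region, height, width) {
  if (is.logical(region) && is.matrix(region)) {
    stopifnot(nrow(region) == height, ncol(region) == width)
    return(region)
  }
  if (is.matrix(region)) region <- list(outer = region, holes = list())
  if (is.list(region) && !is.null(region$outer)) {
    if (is.null(region$holes)) region$holes <- list()
    return(rasterize_polygon(region, height, width))
  }
  stop("`region` must be a logical mask, a ring matrix or a polygon list",
       call. = FALSE)
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged with a union-find over label pairs.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # diagonal down-right
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # diagonal down-left
  e1 <- a1 > 0 & b1 > 0 & a1 != b1
  e2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[e1], b1[e1]), cbind(a2[e2], b2[e2])))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- integer(n); relab[sort(unique(root))] <- seq_along(unique(root))
  out <- lab
  out[lab > 0] <- relab[root[lab[lab > 0]]]
  out
}

# Mean structural similarity (SSIM) of two matrices in [0, 1], 11x11 Gaussian
# window (sigma 1.5), standard stabilising constants.
ssim <- function(x, y, data_range = 1) {
  stopifnot(identical(dim(x), dim(y)))
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  mu_x <- gauss_smooth(x, 1.5); mu_y <- gauss_smooth(y, 1.5)
  sxx <- gauss_smooth(x * x, 1.5) - mu_x^2
  syy <- gauss_smooth(y * y, 1.5) - mu_y^2
  sxy <- gauss_smooth(x * y, 1.5) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(s)
}
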