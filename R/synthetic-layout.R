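#' Generate a synthetic tissue layout with annotated compartments
#'
#' Builds the ground-truth geometry that every synthetic serial section shares:
#' a contiguous tissue mask with a smoothly wobbled boundary, `n_glands`
#' tumor-gland disks (compartment `T`), an invasive-front band around each
#' gland (`IF`), optionally one lymphoid-nodule-like disk (`LN`), and the
#' remaining tissue as distal stroma (`S`). Compartments are stored both as
#' polygons (rings of 0-based `(row, col)` vertices, with holes) and as a
#' rasterized label matrix.
#'
#' @param width,height canvas size in pixels (each at least 256).
#' @param n_glands number of tumor glands to place (at least 1).
#' @param seed integer seed; the layout is a pure function of its arguments.
#' @param ln also place one lymphoid-nodule-like structure when there is room.
#' @return A `tissue_layout` with fields `width`, `height`, `compartments`
#'   (named list of polygon lists), `tissue_mask` (logical H x W), `labels`
#'   (character H x W matrix, `NA` outside tissue) and `seed`.
#' @export
make_tissue_layout <- function(width, height, n_glands = 3, seed = 1, ln = TRUE) {
  stopifnot(width >= 256, height >= 256, n_glands >= 1)
  with_seed(seed, {
    cy <- (height - 1) / 2; cx <- (width - 1) / 2
    theta <- seq(0, 2 * pi, length.out = 97)[-97]
    ph <- runif(4, 0, 2 * pi)
    # radius leaves a canvas margin so realistic section distortions cannot
    # push tissue off the slide
    wob <- 1 + 0.05 * sin(3 * theta + ph[1]) + 0.035 * sin(5 * theta + ph[2])
    tissue_ring <- cbind(cy + 0.42 * height * wob * sin(theta),
                         cx + 0.42 * width * wob * cos(theta))
    tissue_mask <- rasterize_ring(tissue_ring, height, width)

    gr <- max(18, round(0.22 * min(width, height) / sqrt(n_glands + 2)))
    if_w <- round(0.5 * gr)
    outer_r <- gr + if_w
    sep <- 2 * outer_r + 4
    margin <- outer_r + 5

    fits_inside <- function(r0, c0, rad) {
      tt <- seq(0, 2 * pi, length.out = 33)[-33]
      rr <- round(r0 + rad * sin(tt)); cc <- round(c0 + rad * cos(tt))
      if (any(rr < 0 | rr >= height | cc < 0 | cc >= width)) return(FALSE)
      all(tissue_mask[cbind(rr + 1, cc + 1)])
    }

    # rejection sampling with periodic restarts (greedy packing can dead-end)
    centers <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    while (nrow(centers) < n_glands && attempts < 10000L) {
      attempts <- attempts + 1L
      if (attempts %% 500L == 0L) centers <- matrix(numeric(0), 0, 2)
      r0 <- runif(1, margin, height - 1 - margin)
      c0 <- runif(1, margin, width - 1 - margin)
      if (!fits_inside(r0, c0, margin)) next
      if (nrow(centers) &&
          any(sqrt((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2) < sep)) next
      centers <- rbind(centers, c(r0, c0))
    }
    if (nrow(centers) < n_glands) {
      stop(sprintf("cannot place %d glands of radius %d px in a %d x %d canvas; increase the image size or reduce n_glands",
                   n_glands, gr, width, height), call. = FALSE)
    }

    circle_ring <- function(r0, c0, rad, phase) {
      tt <- seq(0, 2 * pi, length.out = 49)[-49]
      w <- 1 + 0.08 * sin(2 * tt + phase)
      cbind(r0 + rad * w * sin(tt), c0 + rad * w * cos(tt))
    }

    t_polys <- list(); if_polys <- list()
    for (g in seq_len(n_glands)) {
      phase <- runif(1, 0, 2 * pi)
      inner <- circle_ring(centers[g, 1], centers[g, 2], gr, phase)
      outer <- circle_ring(centers[g, 1], centers[g, 2], outer_r, phase)
      t_polys[[g]] <- list(outer = inner, holes = list())
      if_polys[[g]] <- list(outer = outer, holes = list(inner))
    }

    ln_polys <- list()
    if (isTRUE(ln)) {
      ln_r <- round(0.6 * gr)
      for (k in seq_len(300L)) {
        r0 <- runif(1, ln_r + 5, height - 1 - ln_r - 5)
        c0 <- runif(1, ln_r + 5, width - 1 - ln_r - 5)
        if (!fits_inside(r0, c0, ln_r + 4)) next
        if (any(sqrt((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2) < outer_r + ln_r + 6)) next
        ln_polys <- list(list(outer = circle_ring(r0, c0, ln_r, runif(1, 0, 2 * pi)),
                              holes = list()))
        break
      }
    }

    labels <- matrix(NA_character_, height, width)
    labels[tissue_mask] <- "S"
    for (p in ln_polys) labels[rasterize_polygon(p, height, width) & tissue_mask] <- "LN"
    for (p in if_polys) labels[rasterize_polygon(p, height, width) & tissue_mask] <- "IF"
    for (p in t_polys)  labels[rasterize_polygon(p, height, width) & tissue_mask] <- "T"

    s_holes <- c(lapply(if_polys, `[[`, "outer"), lapply(ln_polys, `[[`, "outer"))
    compartments <- list(
      T = t_polys,
      IF = if_polys,
      S = list(list(outer = tissue_ring, holes = s_holes))
    )
    if (length(ln_polys)) compartments$LN <- ln_polys

    structure(list(width = as.integer(width), height = as.integer(height),
                   compartments = compartments, tissue_mask = tissue_mask,
                   labels = labels, gland_radius = gr, seed = as.integer(seed)),
              class = "tissue_layout")
  })
}

#' @export
print.tissue_layout <- function(x, ...) {
  cat(sprintf("<tissue_layout> %d x %d px, tissue %.0f%%, compartments: %s (seed %d)\n",
              x$height, x$width, 100 * mean(x$tissue_mask),
              paste(names(x$compartments), collapse = ", "), x$seed))
  invisible(x)
}

#' Per-compartment logical masks of a tissue layout
#'
#' @param layout a `tissue_layout`.
#' @return Named list of logical H x W masks, one per compartment present.
#' @export
compartment_masks <- function(layout) {
  stopifnot(inherits(layout, "tissue_layout"))
  labs <- names(layout$compartments)
  out <- lapply(labs, function(l) !is.na(layout$labels) & layout$labels == l)
  names(out) <- labs
  out
}

#' Plant marker-positive points as per-compartment Poisson processes
#'
#' Simulates, for each marker, the locations of marker-positive cells as an
#' inhomogeneous Poisson process whose intensity is constant within each
#' compartment at the requested rate (points per pixel). When `coloc_rho` is
#' nonzero, markers share a smooth latent log-Gaussian intensity field so that
#' their tile-level densities are spatially correlated; the modulation is
#' mean-preserving, so expected per-compartment counts stay `rate * area`.
#'
#' @param layout a `tissue_layout`.
#' @param rates named list, one element per marker, each a named numeric
#'   vector of intensities (points per pixel) keyed by compartment label.
#' @param coloc_rho latent-field correlation shared across markers, in
#'   \[-1, 1\]; negative values are supported for exactly two markers.
#' @param seed integer seed.
#' @param field_sigma smoothing length (px) of the latent field; defaults to
#'   one eighth of the smaller canvas side.
#' @param field_sd log-scale standard deviation of the latent modulation.
#' @return Named list of `marker_point_set` objects (fields `marker`,
#'   `points` -- n x 2 matrix of 0-based `(row, col)` -- and
#'   `compartment_of`).
#' @export
plant_marker_points <- function(layout, rates, coloc_rho = 0, seed = 1,
                                field_sigma = NULL, field_sd = 0.8) {
  stopifnot(inherits(layout, "tissue_layout"), is.list(rates), length(rates) >= 1)
  if (coloc_rho < -1 || coloc_rho > 1) stop("coloc_rho must lie in [-1, 1]", call. = FALSE)
  if (coloc_rho < 0 && length(rates) > 2)
    stop("negative coloc_rho is only defined for two markers", call. = FALSE)
  known <- names(layout$compartments)
  for (m in names(rates)) {
    r <- rates[[m]]
    if (is.null(names(r)) || !all(names(r) %in% known))
      stop(sprintf("unknown compartment label in rates for marker %s (known: %s)",
                   m, paste(known, collapse = ", ")), call. = FALSE)
    if (any(r < 0)) stop("rates must be nonnegative", call. = FALSE)
  }
  if (is.null(field_sigma)) field_sigma <- min(layout$width, layout$height) / 8

  with_seed(seed, {
    h <- layout$height; w <- layout$width
    masks <- compartment_masks(layout)
    n_mark <- length(rates)
    use_field <- coloc_rho != 0 && n_mark >= 2

    smooth_z <- function() {
      f <- gauss_smooth(matrix(rnorm(h * w), h, w), field_sigma)
      (f - mean(f[layout$tissue_mask])) / stats::sd(f[layout$tissue_mask])
    }
    mults <- vector("list", n_mark)
    if (use_field) {
      L <- smooth_z()
      a <- sqrt(abs(coloc_rho)); b <- sqrt(1 - abs(coloc_rho))
      for (i in seq_len(n_mark)) {
        sgn <- if (coloc_rho < 0 && i == 2L) -1 else 1
        z <- sgn * a * L + b * smooth_z()
        mults[[i]] <- exp(field_sd * z - field_sd^2 / 2)
      }
    }

    out <- vector("list", n_mark)
    names(out) <- names(rates)
    for (i in seq_len(n_mark)) {
      mk <- names(rates)[i]
      pts <- matrix(numeric(0), 0, 2)
      comp <- character(0)
      for (cl in names(rates[[mk]])) {
        lambda <- rates[[mk]][[cl]]
        if (lambda <= 0) next
        idx <- which(masks[[cl]])
        if (!length(idx)) next
        wt <- if (use_field) mults[[i]][idx] else rep(1, length(idx))
        n <- rpois(1, lambda * sum(wt))
        if (n == 0) next
        pick <- sample.int(length(idx), n, replace = TRUE, prob = wt)
        rr <- ((idx[pick] - 1) %% h) + runif(n, -0.5, 0.5)
        cc <- ((idx[pick] - 1) %/% h) + runif(n, -0.5, 0.5)
        pts <- rbind(pts, cbind(pmin(pmax(rr, 0), h - 1), pmin(pmax(cc, 0), w - 1)))
        comp <- c(comp, rep(cl, n))
      }
      colnames(pts) <- c("row", "col")
      out[[i]] <- structure(list(marker = mk, points = pts, compartment_of = comp),
                            class = "marker_point_set")
    }
    out
  })
}

#' @export
print.marker_point_set <- function(x, ...) {
  cat(sprintf("<marker_point_set> %s: %d points (%s)\n", x$marker, nrow(x$points),
              paste(sprintf("%s=%d", names(table(x$compartment_of)),
                            as.integer(table(x$compartment_of))), collapse = ", ")))
  invisible(x)
}
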