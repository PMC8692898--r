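#' Render a synthetic single-marker IHC slide
#'
#' Composes a brightfield IHC image in optical-density space: white slide
#' background, hematoxylin-tinted tissue (denser in tumor glands and lymphoid
#' nodules, with smooth seeded texture so sections carry structure beyond
#' their outline), and a DAB blob of peak optical density `dab_od` centered at
#' each planted marker-positive point. Because composition uses the same
#' Beer-Lambert model and stain vectors as [deconvolve_hdab()], deconvolution
#' recovers the planted DAB signal up to 8-bit quantization.
#'
#' @param layout a `tissue_layout`.
#' @param points a `marker_point_set` (or `NULL` for an unstained section).
#' @param blob_radius radius of one positive cell's DAB blob, pixels (>= 1).
#' @param dab_od peak DAB optical density of a blob (> 0).
#' @param seed integer seed (drives the hematoxylin texture only).
#' @param hema_base baseline hematoxylin OD inside tissue.
#' @param hema_texture amplitude of the smooth hematoxylin texture.
#' @return A [slide_image()] at scale 1.
#' @export
render_ihc_image <- function(layout, points, blob_radius = 5, dab_od = 0.8,
                             seed = 1, hema_base = 0.35, hema_texture = 0.12) {
  stopifnot(inherits(layout, "tissue_layout"), blob_radius >= 1, dab_od > 0)
  h <- layout$height; w <- layout$width
  # the hematoxylin architecture belongs to the tissue block, so serial
  # sections of one layout share it (registration has real correspondences);
  # the per-call seed only adds small section-to-section staining noise
  tex <- with_seed(layout$seed %% 100000 + 17, {
    t0 <- gauss_smooth(matrix(rnorm(h * w), h, w), min(h, w) / 40)
    (t0 - mean(t0)) / stats::sd(t0)
  })
  with_seed(seed, {
    hema <- matrix(0, h, w)
    noise <- gauss_smooth(matrix(rnorm(h * w), h, w), min(h, w) / 60)
    noise <- (noise - mean(noise)) / stats::sd(noise)
    hema[layout$tissue_mask] <- hema_base + hema_texture * tex[layout$tissue_mask] +
      0.03 * noise[layout$tissue_mask]
    lab <- layout$labels
    hema[!is.na(lab) & lab == "T"] <- hema[!is.na(lab) & lab == "T"] + 0.22
    hema[!is.na(lab) & lab == "LN"] <- hema[!is.na(lab) & lab == "LN"] + 0.30
    hema <- pmax(hema, 0)
    hema[layout$tissue_mask] <- pmax(hema[layout$tissue_mask], 0.08)

    dab <- matrix(0, h, w)
    if (!is.null(points) && nrow(points$points) > 0) {
      rad <- ceiling(blob_radius)
      off <- (-rad):rad
      for (i in seq_len(nrow(points$points))) {
        pr <- points$points[i, 1]; pc <- points$points[i, 2]
        rr <- round(pr) + off; cc <- round(pc) + off
        rok <- rr >= 0 & rr < h; cok <- cc >= 0 & cc < w
        if (!any(rok) || !any(cok)) next
        d2 <- outer((rr[rok] - pr)^2, (cc[cok] - pc)^2, `+`)
        prof <- dab_od * pmax(0, 1 - d2 / blob_radius^2)
        dab[rr[rok] + 1, cc[cok] + 1] <- dab[rr[rok] + 1, cc[cok] + 1] + prof
      }
    }

    sv <- hdab_stain_vectors()
    px <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      od <- pmin(hema * sv[1, ch] + dab * sv[2, ch], 2.4)
      px[, , ch] <- round(255 * 10^(-od))
    }
    slide_image(px, marker = if (is.null(points)) "none" else points$marker,
                section_index = 1L, scale = 1)
  })
}

#' Distort a slide with a known smooth deformation
#'
#' Generates the ground-truth deformation for one serial section: a rigid
#' component (rotation about the image center plus a shift) plus a smooth
#' random displacement field (white noise blurred at length `smoothness`,
#' rescaled so its maximum magnitude is exactly `max_disp`). The section image
#' is warped by the total field (pull-back, white fill) and corresponding
#' landmark pairs are sampled on a regular grid inside tissue.
#'
#' The stored field maps distorted-frame (moving) coordinates to original
#' (fixed/reference) coordinates: `fixed = moving + disp[moving]` holds
#' exactly for every landmark pair.
#'
#' @param image a [slide_image()] (the undistorted reference rendering).
#' @param max_disp maximum magnitude of the random displacement, pixels.
#' @param smoothness Gaussian smoothing length of the random field, pixels.
#' @param rigid_part `list(angle = degrees, shift = c(d_row, d_col))`.
#' @param seed integer seed.
#' @param min_landmarks minimum number of landmark pairs to sample.
#' @return List with `image` (the warped [slide_image()]), `field` (the exact
#'   [deformation_field()] used, full resolution) and `landmarks` (data frame
#'   `row_fixed`, `col_fixed`, `row_moving`, `col_moving`, 0-based).
#' @export
apply_deformation <- function(image, max_disp = 10, smoothness = 80,
                              rigid_part = list(angle = 0, shift = c(0, 0)),
                              seed = 1, min_landmarks = 20) {
  stopifnot(inherits(image, "slide_image"), max_disp >= 0, smoothness > 0)
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  with_seed(seed, {
    disp <- array(0, c(h, w, 2))
    if (max_disp > 0) {
      u <- gauss_smooth(matrix(rnorm(h * w), h, w), smoothness)
      v <- gauss_smooth(matrix(rnorm(h * w), h, w), smoothness)
      mag <- sqrt(u^2 + v^2)
      f <- max_disp / max(mag)
      disp[, , 1] <- u * f
      disp[, , 2] <- v * f
    }
    ang <- rigid_part$angle %||% 0
    shift <- rigid_part$shift %||% c(0, 0)
    if (ang != 0 || any(shift != 0)) {
      rp <- affine_disp(c(ang, shift[1], shift[2], 0), h, w)
      disp <- disp + rp
    }

    tissue <- tissue_mask(image)
    field <- deformation_field(disp, scale = image$scale)
    warped <- warp(image, field)
    if (any(tissue)) {
      # tissue "leaves the canvas" when original tissue pixels have no
      # preimage in the moving frame: splat x + D(x) over the canvas and
      # look for uncovered tissue (3x3 dilation absorbs rounding gaps)
      rr <- round(matrix(0:(h - 1), h, w) + disp[, , 1])
      cc <- round(matrix(0:(w - 1), h, w, byrow = TRUE) + disp[, , 2])
      ok <- rr >= 0 & rr < h & cc >= 0 & cc < w
      hit <- matrix(FALSE, h, w)
      hit[cbind(rr[ok] + 1, cc[ok] + 1)] <- TRUE
      pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- hit
      cov <- matrix(FALSE, h, w)
      for (dr in 0:2) for (dc in 0:2) {
        cov <- cov | pad[(1 + dr):(h + dr), (1 + dc):(w + dc)]
      }
      lost <- sum(tissue & !cov) / sum(tissue)
      if (lost > 0.005) {
        stop(sprintf("deformation moves tissue off the canvas (%.1f%% lost)",
                     100 * lost), call. = FALSE)
      }
    }

    # landmarks on a grid in the moving frame, restricted to warped tissue
    stride <- max(8L, round(min(h, w) / 10))
    lms <- NULL
    repeat {
      gr <- seq(stride, h - 1 - stride, by = stride)
      gc <- seq(stride, w - 1 - stride, by = stride)
      pr <- rep(gr, times = length(gc)); pc <- rep(gc, each = length(gr))
      fr <- pr + disp[cbind(pr + 1, pc + 1, 1)]
      fc <- pc + disp[cbind(pr + 1, pc + 1, 2)]
      ok <- fr >= 0 & fr <= h - 1 & fc >= 0 & fc <= w - 1
      ri <- pmin(pmax(round(fr), 0), h - 1) + 1
      ci <- pmin(pmax(round(fc), 0), w - 1) + 1
      ok <- ok & tissue[cbind(ri, ci)]
      lms <- data.frame(row_fixed = fr[ok], col_fixed = fc[ok],
                        row_moving = pr[ok], col_moving = pc[ok])
      if (nrow(lms) >= min_landmarks || stride <= 8L) break
      stride <- max(8L, stride %/% 2)
    }
    list(image = warped, field = field, landmarks = lms)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
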