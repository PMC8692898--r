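#' Downsample a slide to a working resolution
#'
#' Serial-section registration runs at a coarse working scale; slides are
#' antialiased and resized so the longest side is at most `target` pixels,
#' preserving aspect ratio. Images already at or below the target are returned
#' unchanged (no upsampling).
#'
#' @param image a [slide_image()].
#' @param target maximum side length in pixels (at least 64).
#' @return List with `image` (the resized [slide_image()], its `scale` updated)
#'   and `scale` (the resize factor applied, 1 when unchanged).
#' @export
downsample <- function(image, target = 500) {
  stopifnot(inherits(image, "slide_image"), target >= 64)
  d <- dim(image$pixels)
  longest <- max(d[1:2])
  if (longest <= target) return(list(image = image, scale = 1))
  s <- target / longest
  nh <- round(d[1] * s); nw <- round(d[2] * s)
  px <- array(0, c(nh, nw, 3))
  for (ch in 1:3) {
    px[, , ch] <- as.matrix(EBImage::resize(image$pixels[, , ch], w = nh, h = nw,
                                            antialias = TRUE))
  }
  px <- pmin(pmax(px, 0), 255)
  out <- slide_image(px, marker = image$marker,
                     section_index = image$section_index,
                     scale = image$scale * s)
  list(image = out, scale = s)
}

#' Segment tissue from background
#'
#' Foreground tissue is separated from the (near-white) slide background by
#' Otsu thresholding of the inverted grayscale, followed by a
#' largest-components cleanup (components below 10% of the largest are
#' dropped) and hole filling. Deterministic.
#'
#' @param image a [slide_image()] or H x W x 3 array.
#' @return Logical H x W mask; attribute `blank = TRUE` flags an image with no
#'   detectable tissue (the mask is then all `FALSE`).
#' @export
tissue_mask <- function(image) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  stopifnot(is.array(px), length(dim(px)) == 3)
  inv <- 1 - (px[, , 1] + px[, , 2] + px[, , 3]) / (3 * 255)
  if (diff(range(inv)) < 0.02) {
    out <- matrix(FALSE, dim(px)[1], dim(px)[2])
    attr(out, "blank") <- TRUE
    return(out)
  }
  th <- EBImage::otsu(inv, range = c(0, 1))
  mask <- inv > th
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(as.integer(lab))
  if (length(areas)) {
    keep <- which(areas >= 0.1 * max(areas))
    mask <- matrix(as.integer(lab) %in% keep & as.integer(lab) > 0,
                   nrow(mask), ncol(mask))
  }
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  mask <- matrix(as.numeric(filled) > 0.5, nrow(mask), ncol(mask))
  attr(mask, "blank") <- FALSE
  mask
}

#' Warp an image or matrix through a deformation field
#'
#' Pull-back resampling: output pixel `(r, c)` takes the bilinearly
#' interpolated value of the input at `(r, c) + disp[r, c, ]`. Samples falling
#' outside the input canvas are filled with background (white for RGB slides,
#' `fill` for matrices). The output grid is the field's grid.
#'
#' @param x a [slide_image()] or a numeric matrix.
#' @param field a [deformation_field()]; its `scale` must match the image's.
#' @param fill fill value for out-of-canvas samples (matrices only; slides use
#'   white).
#' @return Warped object of the same class as `x`.
#' @export
warp <- function(x, field, fill = 0) UseMethod("warp")

#' @export
warp.slide_image <- function(x, field, fill = 255) {
  stopifnot(inherits(field, "deformation_field"))
  if (abs(x$scale - field$scale) > 1e-6 * max(x$scale, field$scale))
    stop("field scale does not match image scale", call. = FALSE)
  d <- dim(field$disp)
  if (!identical(dim(x$pixels)[1:2], d[1:2]))
    stop("field grid does not match image dimensions", call. = FALSE)
  rr <- matrix(0:(d[1] - 1), d[1], d[2]) + field$disp[, , 1]
  cc <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE) + field$disp[, , 2]
  px <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    px[, , ch] <- matrix(bilinear_sample(x$pixels[, , ch], rr, cc, fill = fill),
                         d[1], d[2])
  }
  slide_image(pmin(pmax(px, 0), 255), marker = x$marker,
              section_index = x$section_index, scale = x$scale)
}

#' @export
warp.matrix <- function(x, field, fill = 0) {
  stopifnot(inherits(field, "deformation_field"))
  d <- dim(field$disp)
  if (!identical(dim(x), d[1:2]))
    stop("field grid does not match matrix dimensions", call. = FALSE)
  rr <- matrix(0:(d[1] - 1), d[1], d[2]) + field$disp[, , 1]
  cc <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE) + field$disp[, , 2]
  matrix(bilinear_sample(x * 1, rr, cc, fill = fill), d[1], d[2])
}

#' Upsample a deformation field to a finer scale
#'
#' Registration produces fields at the downsampled working scale; to warp the
#' full-resolution slide the field grid is bilinearly resampled to the target
#' size and the displacement magnitudes are multiplied by the scale ratio.
#'
#' @param field a [deformation_field()].
#' @param to_scale target scale (must be at least `field$scale`).
#' @param dim optional integer target grid `c(rows, cols)`; defaults to
#'   `round(dim(field) * to_scale / field$scale)`.
#' @return A [deformation_field()] at `to_scale`.
#' @export
upsample_field <- function(field, to_scale, dim = NULL) {
  stopifnot(inherits(field, "deformation_field"))
  if (to_scale < field$scale) stop("to_scale must be >= field scale", call. = FALSE)
  factor <- to_scale / field$scale
  d <- base::dim(field$disp)
  if (is.null(dim)) dim <- round(d[1:2] * factor)
  if (identical(as.integer(dim), d[1:2]) && abs(factor - 1) < 1e-12) return(field)
  fr <- d[1] / dim[1]; fc <- d[2] / dim[2]
  rr <- matrix(((0:(dim[1] - 1)) + 0.5) * fr - 0.5, dim[1], dim[2])
  cc <- matrix(((0:(dim[2] - 1)) + 0.5) * fc - 0.5, dim[1], dim[2], byrow = TRUE)
  disp <- array(0, c(dim[1], dim[2], 2))
  mag <- c(to_scale / field$scale, to_scale / field$scale)
  for (k in 1:2) {
    disp[, , k] <- matrix(bilinear_sample(field$disp[, , k], rr, cc, fill = NA_real_),
                          dim[1], dim[2]) * mag[k]
  }
  deformation_field(disp, scale = to_scale)
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration for the inverse displacement `G` of `D`, i.e.
#' `G(x) = -D(x + G(x))`, so that warping by `D` then by `G` is close to the
#' identity for smooth fields.
#'
#' @param field a [deformation_field()].
#' @param n_iter maximum fixed-point iterations.
#' @param tol stop when the maximum update falls below this (pixels).
#' @return The inverse [deformation_field()] at the same scale.
#' @export
invert_field <- function(field, n_iter = 50, tol = 1e-3) {
  d <- dim(field$disp)
  r0 <- matrix(0:(d[1] - 1), d[1], d[2])
  c0 <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
  g1 <- matrix(0, d[1], d[2]); g2 <- matrix(0, d[1], d[2])
  for (k in seq_len(n_iter)) {
    s1 <- matrix(bilinear_sample(field$disp[, , 1], r0 + g1, c0 + g2, fill = NA_real_), d[1], d[2])
    s2 <- matrix(bilinear_sample(field$disp[, , 2], r0 + g1, c0 + g2, fill = NA_real_), d[1], d[2])
    delta <- max(abs(-s1 - g1), abs(-s2 - g2))
    g1 <- -s1; g2 <- -s2
    if (delta < tol) break
  }
  deformation_field(array(c(g1, g2), c(d[1], d[2], 2)), scale = field$scale)
}

# --- internal: registration machinery ---------------------------------------

# Absorbance feature image used for alignment: stain-agnostic inverted
# grayscale so marker-dependent color does not drive the match.
feature_image <- function(image) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  1 - (px[, , 1] + px[, , 2] + px[, , 3]) / (3 * 255)
}

# Dense displacement field of a similarity transform (rotation about the grid
# center + uniform scale + translation), as an H x W x 2 array.
affine_disp <- function(par, h, w) {
  th <- par[1] * pi / 180; s <- exp(par[4])
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  r0 <- matrix(0:(h - 1), h, w) - cy
  c0 <- matrix(0:(w - 1), h, w, byrow = TRUE) - cx
  ar <- s * (cos(th) * r0 - sin(th) * c0) + cy + par[2]
  ac <- s * (sin(th) * r0 + cos(th) * c0) + cx + par[3]
  array(c(ar - r0 - cy, ac - c0 - cx), c(h, w, 2))
}

sample_by_disp <- function(m, disp, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  rr <- matrix(0:(h - 1), h, w) + disp[, , 1]
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE) + disp[, , 2]
  matrix(bilinear_sample(m, rr, cc, fill = fill), h, w)
}

metric_value <- function(a, b, metric) {
  if (metric == "mse") return(mean((a - b)^2))
  # mutual information on a 32-bin joint histogram (maximized -> negated)
  nb <- 32L
  ai <- pmin(pmax(floor(a * nb) + 1L, 1L), nb)
  bi <- pmin(pmax(floor(b * nb) + 1L, 1L), nb)
  jt <- table(factor(ai, levels = 1:nb), factor(bi, levels = 1:nb)) / length(a)
  pa <- rowSums(jt); pb <- colSums(jt)
  nz <- jt > 0
  -sum(jt[nz] * log(jt[nz] / outer(pa, pb)[nz]))
}

mask_centroid <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(c(NA_real_, NA_real_))
  h <- nrow(mask)
  c(mean((idx - 1) %% h), mean((idx - 1) %/% h))
}

registration_failure <- function(msg, diagnostics = list()) {
  stop(errorCondition(msg, class = "registration_failure", diagnostics = diagnostics))
}

# Multi-resolution similarity-transform search (Nelder-Mead per level).
affine_register <- function(mov_f, fix_f, metric = "mse", pyramid = c(4, 2, 1),
                            init = c(0, 0, 0, 0)) {
  par <- init
  for (fct in pyramid) {
    h <- max(32L, round(nrow(fix_f) / fct)); w <- max(32L, round(ncol(fix_f) / fct))
    fl <- as.matrix(EBImage::resize(fix_f, w = h, h = w, antialias = TRUE))
    ml <- as.matrix(EBImage::resize(mov_f, w = h, h = w, antialias = TRUE))
    sc <- h / nrow(fix_f)
    obj <- function(p) {
      d <- affine_disp(c(p[1], p[2] * sc, p[3] * sc, p[4]), h, w)
      v <- metric_value(sample_by_disp(ml, d), fl, metric)
      if (!is.finite(v)) Inf else v
    }
    opt <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = if (fct >= 4) 300 else 150,
                                       reltol = 1e-7))
    par <- opt$par
  }
  par
}

grad2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  gr[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  gc[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  list(r = gr, c = gc)
}

# Demons-style nonrigid refinement of a displacement field at one resolution.
# Symmetric force (mean of fixed and warped-moving gradients), per-iteration
# step cap, Gaussian regularization of the total field.
demons_refine <- function(mov_f, fix_f, disp, n_iter = 100, sigma = 3,
                          step_max = 1, patience = 15) {
  best <- disp; best_mse <- Inf; since <- 0L
  trace <- numeric(0)
  eps <- 1e-6
  gf <- grad2(fix_f)
  for (it in seq_len(n_iter)) {
    mw <- sample_by_disp(mov_f, disp)
    diffi <- fix_f - mw
    mse <- mean(diffi^2)
    trace <- c(trace, mse)
    if (mse < best_mse - 1e-10) { best <- disp; best_mse <- mse; since <- 0L }
    else { since <- since + 1L; if (since >= patience) break }
    gm <- grad2(mw)
    gr <- (gf$r + gm$r) / 2
    gc <- (gf$c + gm$c) / 2
    den <- gr^2 + gc^2 + diffi^2 + eps
    ur <- diffi * gr / den
    uc <- diffi * gc / den
    mag <- sqrt(ur^2 + uc^2)
    capf <- ifelse(mag > step_max, step_max / mag, 1)
    disp[, , 1] <- gauss_smooth(disp[, , 1] + ur * capf, sigma)
    disp[, , 2] <- gauss_smooth(disp[, , 2] + uc * capf, sigma)
  }
  list(disp = best, mse = best_mse, trace = trace)
}

# Coarse-to-fine demons: run at each pyramid level, upscaling the field.
demons_pyramid <- function(mov_f, fix_f, disp_init, levels = c(4, 2, 1),
                           iters = c(150, 80, 40), sigma = 3, step_max = 1) {
  h <- nrow(fix_f); w <- ncol(fix_f)
  disp <- NULL; trace <- numeric(0)
  for (k in seq_along(levels)) {
    lev <- levels[k]
    hl <- max(32L, round(h / lev)); wl <- max(32L, round(w / lev))
    fl <- as.matrix(EBImage::resize(fix_f, w = hl, h = wl, antialias = TRUE))
    ml <- as.matrix(EBImage::resize(mov_f, w = hl, h = wl, antialias = TRUE))
    sc <- hl / h
    if (is.null(disp)) {
      dl <- array(0, c(hl, wl, 2))
      rr <- matrix(((0:(hl - 1)) + 0.5) / sc - 0.5, hl, wl)
      cc <- matrix(((0:(wl - 1)) + 0.5) / (wl / w) - 0.5, hl, wl, byrow = TRUE)
      dl[, , 1] <- matrix(bilinear_sample(disp_init[, , 1], rr, cc, fill = NA_real_), hl, wl) * sc
      dl[, , 2] <- matrix(bilinear_sample(disp_init[, , 2], rr, cc, fill = NA_real_), hl, wl) * sc
    } else {
      prev <- deformation_field(disp, scale = prev_sc)
      dl <- upsample_field(prev, to_scale = sc, dim = c(hl, wl))$disp
    }
    dm <- demons_refine(ml, fl, dl, n_iter = iters[min(k, length(iters))],
                        sigma = sigma, step_max = step_max)
    disp <- dm$disp; prev_sc <- sc
    trace <- c(trace, dm$trace)
  }
  if (!identical(dim(disp)[1:2], c(h, w))) {
    disp <- upsample_field(deformation_field(disp, scale = prev_sc),
                           to_scale = 1, dim = c(h, w))$disp
  }
  list(disp = disp, trace = trace, mse = tail(trace, 1))
}

#' Register one slide onto a fixed reference slide
#'
#' Two-stage intensity-based registration on tissue absorbance (inverted
#' grayscale, so stain color does not drive the alignment): a multi-resolution
#' similarity-transform search (mean-squared-error metric by default, mutual
#' information as an option) followed by demons-style dense nonrigid
#' refinement with Gaussian field regularization. The returned field is a
#' pull-back displacement at the (downsampled) input scale. The tissue-mask
#' Dice coefficient is never allowed to decrease: if the nonrigid step
#' degrades Dice the affine field is returned, and if even that is worse than
#' no registration the zero field is returned with a report flag.
#'
#' @param moving,fixed [slide_image()]s at a comparable (downsampled) scale.
#' @param config list of options: `metric` ("mse" or "mi"), `demons` (logical),
#'   `n_demons`, `sigma_demons` (px), `step_max` (px/iteration), `pyramid`
#'   (affine resolution divisors).
#' @return List with `field` (a [deformation_field()]) and `report` (a
#'   `registration_report`: `dice_before`, `dice_after`, `method`,
#'   `similarity_metric_trace`).
#' @export
register_pair <- function(moving, fixed, config = list()) {
  stopifnot(inherits(moving, "slide_image"), inherits(fixed, "slide_image"))
  cfg <- modifyList(list(metric = "mse", demons = TRUE,
                         demons_levels = c(4, 2, 1),
                         demons_iters = c(150, 80, 40),
                         sigma_demons = 3, step_max = 1, pyramid = c(4, 2, 1)),
                    config)
  if (!is.null(config$n_demons))   # single-level iteration override
    cfg$demons_iters <- pmin(cfg$demons_iters, config$n_demons)
  mov_f <- feature_image(moving); fix_f <- feature_image(fixed)
  mask_m <- tissue_mask(moving); mask_f <- tissue_mask(fixed)
  if (!sum(mask_m) || !sum(mask_f))
    registration_failure("no tissue detected in one of the images",
                         list(tissue_moving = sum(mask_m), tissue_fixed = sum(mask_f)))
  h <- nrow(fix_f); w <- ncol(fix_f)
  if (!identical(dim(mov_f), dim(fix_f)))
    stop("moving and fixed images must share a grid; downsample both first", call. = FALSE)
  dice_before <- dice_coefficient(mask_f, mask_m)

  init <- c(0, mask_centroid(mask_m) - mask_centroid(mask_f), 0)
  par <- affine_register(mov_f, fix_f, metric = cfg$metric, pyramid = cfg$pyramid,
                         init = init)
  disp_aff <- affine_disp(par, h, w)
  warp_mask <- function(disp) sample_by_disp(mask_m * 1, disp) > 0.5
  dice_aff <- dice_coefficient(mask_f, warp_mask(disp_aff))
  if (!any(warp_mask(disp_aff) & mask_f))
    registration_failure("no tissue overlap after affine initialization",
                         list(par = par, dice_before = dice_before))

  trace <- metric_value(sample_by_disp(mov_f, disp_aff), fix_f, "mse")
  method <- "affine"; disp <- disp_aff; dice_after <- dice_aff
  if (isTRUE(cfg$demons)) {
    dm <- demons_pyramid(mov_f, fix_f, disp_aff, levels = cfg$demons_levels,
                         iters = cfg$demons_iters,
                         sigma = cfg$sigma_demons, step_max = cfg$step_max)
    trace <- c(trace, dm$trace)
    dice_dem <- dice_coefficient(mask_f, warp_mask(dm$disp))
    if (dice_dem >= dice_aff - 1e-9) {
      method <- "affine+demons"; disp <- dm$disp; dice_after <- dice_dem
    }
  }
  if (dice_after < dice_before) {
    method <- "identity_fallback"
    disp <- array(0, c(h, w, 2))
    dice_after <- dice_before
  }
  if (!all(is.finite(disp)))
    registration_failure("registration produced non-finite displacements")
  report <- structure(list(dice_before = dice_before, dice_after = dice_after,
                           method = method, affine_par = par,
                           similarity_metric_trace = trace),
                      class = "registration_report")
  list(field = deformation_field(disp, scale = fixed$scale), report = report)
}

#' @export
print.registration_report <- function(x, ...) {
  metric <- if (length(x$similarity_metric_trace))
    sprintf(", final metric %.3g", tail(x$similarity_metric_trace, 1)) else ""
  cat(sprintf("<registration_report> %s: Dice %.4f -> %.4f%s\n",
              x$method, x$dice_before, x$dice_after, metric))
  invisible(x)
}

#' Mean landmark target registration error of a recovered field
#'
#' Landmarks are pairs of corresponding 0-based full-resolution coordinates in
#' the reference (`row_fixed`, `col_fixed`) and moving (`row_moving`,
#' `col_moving`) frames. Each fixed landmark is mapped through the field
#' (after rescaling coordinates to the field's scale) and compared with its
#' true moving position; the mean Euclidean error, in pixels at the field's
#' scale, is returned.
#'
#' @param field a [deformation_field()].
#' @param landmarks data frame with columns `row_fixed`, `col_fixed`,
#'   `row_moving`, `col_moving` at original (scale-1) resolution.
#' @return Mean TRE in pixels at `field$scale`.
#' @export
landmark_tre <- function(field, landmarks) {
  s <- field$scale
  to_s <- function(p) (p + 0.5) * s - 0.5
  rf <- to_s(landmarks$row_fixed); cf <- to_s(landmarks$col_fixed)
  rm_ <- to_s(landmarks$row_moving); cm <- to_s(landmarks$col_moving)
  dr <- bilinear_sample(field$disp[, , 1], rf, cf, fill = NA_real_)
  dc <- bilinear_sample(field$disp[, , 2], rf, cf, fill = NA_real_)
  mean(sqrt((rf + dr - rm_)^2 + (cf + dc - cm)^2))
}

#' Register a stack of serial sections onto a reference slide
#'
#' Every section is downsampled to the working resolution, registered onto
#' the reference section (by default the centroid slide, i.e. the middle of
#' the stack, lower index on ties), and the recovered field is upsampled to
#' the reference's full resolution so the original scans can be warped into
#' one frame.
#'
#' @param images list of [slide_image()]s (at least two).
#' @param reference `"centroid"` or a 1-based section index.
#' @param config registration options, see [register_pair()]; additionally
#'   `downsample_target` (default 500).
#' @return List with `fields` (full-resolution [deformation_field()]s, the
#'   zero field for the reference), `reports`, and `reference` (the index
#'   used).
#' @export
register_stack <- function(images, reference = "centroid", config = list()) {
  stopifnot(is.list(images), length(images) >= 2)
  n <- length(images)
  ref <- if (identical(reference, "centroid")) floor((n + 1) / 2) else as.integer(reference)
  stopifnot(ref >= 1, ref <= n)
  target <- if (is.null(config$downsample_target)) 500 else config$downsample_target
  fix_ds <- downsample(images[[ref]], target)
  dref <- dim(images[[ref]]$pixels)
  fields <- vector("list", n); reports <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == ref) {
      fields[[i]] <- zero_field(dref[1], dref[2], scale = images[[ref]]$scale)
      reports[[i]] <- structure(list(dice_before = 1, dice_after = 1,
                                     method = "reference",
                                     similarity_metric_trace = numeric(0)),
                                class = "registration_report")
      next
    }
    mov_ds <- downsample(images[[i]], target)
    res <- tryCatch(register_pair(mov_ds$image, fix_ds$image, config = config),
                    error = function(e) {
                      stop(sprintf("registration failed for section %d: %s",
                                   i, conditionMessage(e)), call. = FALSE)
                    })
    fields[[i]] <- upsample_field(res$field, to_scale = images[[ref]]$scale,
                                  dim = dref[1:2])
    reports[[i]] <- res$report
  }
  list(fields = fields, reports = reports, reference = ref)
}
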