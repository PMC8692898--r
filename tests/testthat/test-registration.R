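test_that("downsample preserves aspect ratio, never upsamples, keeps constancy", {
  big <- slide_image(array(128, c(1000, 800, 3)))
  ds <- downsample(big, target = 100)
  expect_identical(dim(ds$image$pixels)[1:2], c(100L, 80L))
  expect_equal(ds$scale, 0.1)
  expect_equal(ds$image$scale, 0.1)
  # uniform input stays uniform
  expect_lt(diff(range(ds$image$pixels)), 1e-6)
  small <- slide_image(array(200, c(300, 300, 3)))
  ds2 <- downsample(small, target = 500)
  expect_identical(ds2$image$pixels, small$pixels)
  expect_equal(ds2$scale, 1)
})

test_that("tissue segmentation matches the synthetic ground truth and is stable", {
  lay <- fix_layout()
  img <- fix_slide()
  m <- tissue_mask(img)
  expect_gte(serialihc:::dice_coefficient(m, lay$tissue_mask), 0.98)
  # blank slide -> empty mask, flagged
  blank <- slide_image(array(255, c(128, 128, 3)))
  mb <- tissue_mask(blank)
  expect_false(any(mb))
  expect_true(attr(mb, "blank"))
  # idempotence: whitening the background of a masked render changes nothing
  px <- img$pixels
  for (ch in 1:3) { p <- px[, , ch]; p[!m] <- 255; px[, , ch] <- p }
  m2 <- tissue_mask(slide_image(px))
  expect_identical(m, m2, ignore_attr = TRUE)
})

test_that("field upsampling scales grid and magnitudes together", {
  const <- deformation_field(array(rep(c(10, 0), each = 50 * 50), c(50, 50, 2)),
                             scale = 0.1)
  up <- upsample_field(const, to_scale = 1)
  expect_identical(dim(up$disp)[1:2], c(500L, 500L))
  expect_true(all(abs(up$disp[, , 1] - 100) < 1e-9))
  expect_true(all(abs(up$disp[, , 2]) < 1e-9))
  expect_equal(up$scale, 1)
  # upsampling to the same scale is the identity
  same <- upsample_field(const, to_scale = 0.1)
  expect_identical(same$disp, const$disp)
  # smooth analytic field: coarse sampling then upsampling reproduces it
  h <- 200; w <- 200
  fr <- function(r, c) 6 * sin(2 * pi * r / h) * cos(2 * pi * c / w)
  fc <- function(r, c) 4 * cos(2 * pi * r / h)
  s <- 0.25; hc <- h * s; wc <- w * s
  rc <- ((0:(hc - 1)) + 0.5) / s - 0.5
  cc <- ((0:(wc - 1)) + 0.5) / s - 0.5
  coarse <- array(0, c(hc, wc, 2))
  coarse[, , 1] <- outer(rc, cc, fr) * s
  coarse[, , 2] <- outer(rc, cc, Vectorize(function(r, c) fc(r, c))) * s
  up2 <- upsample_field(deformation_field(coarse, scale = s), to_scale = 1)
  full1 <- outer(0:(h - 1), 0:(w - 1), fr)
  full2 <- outer(0:(h - 1), 0:(w - 1), Vectorize(function(r, c) fc(r, c)))
  expect_lt(max(abs(up2$disp[, , 1] - full1)), 0.5)
  expect_lt(max(abs(up2$disp[, , 2] - full2)), 0.5)
})

test_that("warping obeys the pull-back convention", {
  img <- fix_slide()
  d <- dim(img$pixels)
  zf <- serialihc:::zero_field(d[1], d[2])
  expect_identical(warp(img, zf)$pixels, img$pixels)
  # constant integer shift: out[r, c] = in[r + 5, c + 3]
  sh <- serialihc:::zero_field(d[1], d[2])
  sh$disp[, , 1] <- 5; sh$disp[, , 2] <- 3
  w <- warp(img, sh)
  expect_equal(w$pixels[1:(d[1] - 5), 1:(d[2] - 3), ],
               img$pixels[6:d[1], 4:d[2], ])
  # out-of-canvas fill is white
  expect_true(all(w$pixels[d[1], , ] == 255))
})

test_that("warping by a field and then its inverse restores the slide", {
  img <- fix_slide()
  res <- apply_deformation(img, max_disp = 8, smoothness = 60, seed = 9)
  inv <- invert_field(res$field)
  back <- warp(res$image, inv)
  f0 <- serialihc:::feature_image(img)
  f1 <- serialihc:::feature_image(back)
  expect_gte(serialihc:::ssim(f0, f1), 0.98)
})

test_that("registering an image to itself yields a near-zero field", {
  ds <- downsample(fix_slide(), 250)$image
  res <- register_pair(ds, ds, config = list(n_demons = 30))
  mag <- sqrt(res$field$disp[, , 1]^2 + res$field$disp[, , 2]^2)
  expect_lt(mean(mag), 0.1)
  expect_gte(res$report$dice_after, res$report$dice_before)
})

test_that("a rigid shift is recovered with sub-pixel landmark error", {
  img <- fix_slide()
  res <- apply_deformation(img, max_disp = 0, smoothness = 50,
                           rigid_part = list(angle = 0, shift = c(10, 0)), seed = 1)
  reg <- register_pair(res$image, img, config = list(n_demons = 40))
  expect_lt(landmark_tre(reg$field, res$landmarks), 1)
  expect_gte(reg$report$dice_after, reg$report$dice_before)
})

test_that("stack registration picks the centroid reference and handles identity stacks", {
  img <- downsample(fix_slide(), 220)$image
  stack <- list(img, img, img, img, img)
  res <- register_stack(stack, reference = "centroid",
                        config = list(n_demons = 5, downsample_target = 220))
  expect_identical(res$reference, 3)       # middle of five, ties -> lower
  for (f in res$fields) {
    mag <- sqrt(f$disp[, , 1]^2 + f$disp[, , 2]^2)
    expect_lt(mean(mag), 0.1)
  }
  res4 <- register_stack(list(img, img, img, img), reference = "centroid",
                         config = list(n_demons = 1, downsample_target = 220))
  expect_identical(res4$reference, 2)
})

test_that("registration failures carry diagnostics", {
  blank <- slide_image(array(255, c(128, 128, 3)))
  expect_error(register_pair(blank, blank), class = "registration_failure")
})
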