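# Reference preprocessing, histogram matching, shift/homography detection,
# SSIM-based QC and overlap cropping.

test_that("preprocess_reference applies the clip/z-score/blur/threshold chain", {
  # compact bright nuclei (~25% of pixels) on zero background: everything
  # below the 70th percentile of the blurred image is set exactly to 0
  set.seed(1)
  img <- matrix(0, 60, 60)
  nuc <- matrix(FALSE, 60, 60)
  for (ctr in list(c(15, 15), c(15, 45), c(45, 15), c(45, 45), c(30, 30))) {
    nuc <- nuc | outer((1:60) - ctr[1], (1:60) - ctr[2],
                       function(a, b) a^2 + b^2 <= 60)
  }
  img[nuc] <- runif(sum(nuc), 150, 255)
  out <- preprocess_reference(img, zero_below_pct = 70)
  expect_gte(mean(out == 0), 0.7) # at least the bottom 70% zeroed
  far_bg <- !nuc & !(EBImage::dilate(EBImage::Image(nuc * 1),
                                     EBImage::makeBrush(9, "disc")) > 0)
  expect_true(all(out[far_bg] == 0)) # background away from nuclei exactly 0
  expect_true(all(out >= 0 & out <= 1))
  # with no clipping, no blur and no thresholding this is an affine rescale
  x <- matrix(runif(100), 10, 10)
  out2 <- preprocess_reference(x, clip_low_pct = 0, clip_high_pct = 100,
                               blur_sigma = 0, zero_below_pct = 0)
  expect_equal(out2, rescale01(x), tolerance = 1e-12)
  # percentile clipping uses linear interpolation between order statistics
  ramp <- matrix(0:99, 10, 10)
  b <- percentile(ramp, c(1, 99.9))
  expect_equal(b[1], 0.99)
  expect_equal(b[2], 98.901)
  # constant image degrades gracefully
  expect_warning(res <- preprocess_reference(matrix(5, 8, 8)), "constant")
  expect_true(all(res == 0))
})

test_that("match_histogram is a monotone quantile mapping", {
  set.seed(2)
  ref <- matrix(runif(400), 20, 20)
  expect_equal(match_histogram(ref, ref), ref, tolerance = 1e-10)
  shifted <- ref + 100
  expect_equal(match_histogram(shifted, ref), ref, tolerance = 1e-6)
  # binary {0,1} mapped onto binary {0,5} with equal proportions
  mv <- matrix(rep(c(0, 1), each = 50), 10, 10)
  rf <- matrix(rep(c(0, 5), each = 50), 10, 10)
  out <- match_histogram(mv, rf)
  expect_setequal(unique(as.vector(out)), c(0, 5))
  expect_equal(out[mv == 1], rep(5, 50))
})

test_that("detect_shift recovers planted integer and subpixel shifts", {
  tex <- speckle_texture(128, sigma = 1, seed = 3)
  expect_equal(detect_shift(tex, tex), c(0, 0))
  expect_equal(detect_shift(tex, roll_matrix(tex, c(7, -3))), c(7, -3))
  # planted integer shifts with zero fill, across magnitudes
  set.seed(4)
  for (i in 1:5) {
    d <- sample(-20:20, 2, TRUE)
    expect_equal(detect_shift(tex, apply_shift(tex, d)), d)
  }
  # subpixel: band-limited texture, upsample 5, within 0.2 px per axis
  Hm <- rbind(c(1, 0, 2.4), c(0, 1, 0), c(0, 0, 1))
  d <- detect_shift(tex, warp_projective(tex, Hm), upsample = 5)
  expect_lt(max(abs(d - c(2.4, 0))), 0.2)
  expect_error(detect_shift(matrix(0, 8, 8), matrix(0, 8, 8)), "degenerate")
})

test_that("detect_homography recovers identity, small rotations, and falls back", {
  tex <- speckle_texture(192, sigma = 1.5, seed = 5)
  H0 <- detect_homography(tex, tex)
  expect_lt(norm(H0 - diag(3), "F"), 1e-3)
  # planted 1-degree rotation about the centre
  th <- pi / 180
  ctr <- (nrow(tex) - 1) / 2
  R <- rbind(c(cos(th), -sin(th), ctr - cos(th) * ctr + sin(th) * ctr),
             c(sin(th), cos(th), ctr - sin(th) * ctr - cos(th) * ctr),
             c(0, 0, 1))
  Hm <- detect_homography(tex, warp_projective(tex, R))
  ang <- abs(atan2(Hm[2, 1], Hm[1, 1]) * 180 / pi)
  expect_lt(abs(ang - 1), 0.1)
  # featureless image: identity with fallback flag
  Hf <- detect_homography(matrix(1, 64, 64), matrix(1, 64, 64))
  expect_true(isTRUE(attr(Hf, "fallback")))
  expect_equal(unclass(Hf)[1:3, 1:3], diag(3), ignore_attr = TRUE)
})

test_that("apply_shift / apply_transform shift stacks with zero fill", {
  x <- matrix(1, 10, 10)
  y <- apply_shift(x, c(3, 0))
  expect_true(all(y[1:3, ] == 0))
  expect_true(all(y[4:10, ] == 1))
  tex <- speckle_texture(64, seed = 6)
  st <- multiplex_image(array(tex, c(64, 64, 1)),
                        channel_meta("a", 1, "w", is_reference = TRUE))
  res <- registration_result(c(2, -1), 0.5, 0.9)
  out <- apply_transform(st, res)
  expect_equal(out$data[5, 5, 1], tex[3, 6])
  ident <- registration_result(c(0, 0), 0.5, 0.9)
  expect_equal(apply_transform(st, ident)$data, st$data)
  # shift then inverse shift restores the interior
  fwd <- apply_shift(tex, c(1.5, -2.5))
  back <- apply_shift(fwd, c(-1.5, 2.5))
  expect_equal(back[10:50, 10:50], tex[10:50, 10:50], tolerance = 0.05)
})

test_that("registration QC flags follow the four review rules", {
  f <- function(b, a, s) sort(registration_flags(b, a, s))
  expect_equal(f(0.50, 0.45, c(2, 2)),
               sort(c("decreased", "low_ssim_small_improvement")))
  expect_equal(f(0.40, 0.85, c(12, -8)), character(0))
  expect_equal(f(0.10, 0.25, c(400, 0)), sort(c("low_ssim", "large_offset")))
  # accepted <=> no flags; pure function of its inputs
  r <- registration_result(c(1, 1), 0.4, 0.85)
  expect_true(r$accepted)
  expect_length(r$flags, 0)
  r2 <- registration_result(c(1, 1), 0.78, 0.79)
  expect_false(r2$accepted) # below 0.8 with only 0.01 improvement
  expect_equal(r2$flags, "low_ssim_small_improvement")
})

test_that("ssim is 1 for identical images and decreases under perturbation", {
  tex <- speckle_texture(64, seed = 8)
  expect_equal(ssim(tex, tex), 1)
  noisy <- tex + matrix(rnorm(64 * 64, 0, 0.2), 64, 64)
  expect_lt(ssim(tex, noisy), ssim(tex, tex))
  shifted <- apply_shift(tex, c(5, 5))
  expect_lt(ssim(tex, shifted), 0.9)
})

test_that("crop_to_overlap implements both policies within bounds", {
  # global max offset: remove ceil(max |d|) from every side (0-based 5..94)
  w <- crop_to_overlap(list(c(0, 0), c(5, -2)), "global_max_offset", c(100, 100))
  expect_equal(w$rows, c(6L, 95L))
  expect_equal(w$cols, c(6L, 95L))
  # all-zero shifts keep the full frame
  w0 <- crop_to_overlap(list(c(0, 0)), "global_max_offset", c(100, 100))
  expect_equal(w0$rows, c(1L, 100L))
  # per-FOV overlap: intersection rectangle (0-based rows 10..89)
  w2 <- crop_to_overlap(list(c(10, 0), c(-10, 0)), "per_fov_overlap", c(100, 100))
  expect_equal(w2$rows, c(11L, 90L))
  expect_equal(w2$cols, c(1L, 100L))
  # windows never exceed bounds on random shifts
  set.seed(9)
  for (i in 1:20) {
    sh <- matrix(runif(6, -12, 12), 3, 2)
    for (mode in c("global_max_offset", "per_fov_overlap")) {
      wi <- crop_to_overlap(sh, mode, c(60, 80))
      expect_true(wi$rows[1] >= 1 && wi$rows[2] <= 60)
      expect_true(wi$cols[1] >= 1 && wi$cols[2] <= 80)
    }
  }
  expect_error(crop_to_overlap(list(c(200, 0), c(-200, 0)), "per_fov_overlap",
                               c(100, 100), fov_id = "fovX"), "fovX")
})
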