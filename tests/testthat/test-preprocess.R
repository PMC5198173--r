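test_that("field-of-view detection recovers a stamped disc and rejects degenerate frames", {
  img <- disc_image(576, 768, center = c(288, 384), radius = 200)
  fov <- detect_fov(img)
  expect_lt(abs(fov$radius - 200), 3)
  expect_lt(max(abs(fov$center - c(288, 384))), 2)

  black <- fundus_image(array(0, dim = c(64, 64, 3)))
  expect_error(detect_fov(black), "no field of view")

  bright <- fundus_image(array(0.8, dim = c(64, 64, 3)))
  expect_error(detect_fov(bright), "no field of view")
})

test_that("quality gate passes vessel-bearing scenes and rejects flat or attenuated ones", {
  flat <- disc_image(400, 400, c(199.5, 199.5), 160)
  rep_flat <- assess_quality(flat, detect_fov(flat))
  expect_false(rep_flat$gradable)
  expect_true("low vessel contrast" %in% rep_flat$reasons)

  sc <- generate_scene(scene_params(seed = 7))
  rep_ok <- assess_quality(sc$image, detect_fov(sc$image))
  expect_true(rep_ok$gradable)

  weak <- generate_scene(scene_params(seed = 7,
                                      vessel_depth_range = c(8e-4, 1.4e-3)))
  rep_weak <- assess_quality(weak$image, detect_fov(weak$image))
  expect_false(rep_weak$gradable)
  expect_true("low vessel contrast" %in% rep_weak$reasons)
  expect_gt(rep_ok$vessel_contrast, rep_weak$vessel_contrast)
})

test_that("standardization rescales any native resolution to the canonical field diameter", {
  # high-resolution native frame (e.g. 3888 x 2592 cameras)
  big <- disc_image(2592, 3888, c(1295.5, 1943.5), 1250)
  fov_b <- detect_fov(big)
  std_b <- standardize(big, fov_b)
  expect_lt(abs(2 * std_b$fov$radius - 768), 1)
  expect_equal(std_b$scale_factor, 768 / (2 * fov_b$radius))

  # low-resolution native frame (768 x 576 cameras): upscaling
  small <- disc_image(576, 768, c(287.5, 383.5), 260)
  fov_s <- detect_fov(small)
  std_s <- standardize(small, fov_s)
  expect_lt(abs(2 * std_s$fov$radius - 768), 1)
  expect_equal(std_s$scale_factor, 768 / (2 * fov_s$radius))
  expect_gt(std_s$scale_factor, 1)

  tiny <- disc_image(64, 64, c(31.5, 31.5), 20)
  expect_error(standardize(tiny, detect_fov(tiny)), "too small")
})

test_that("standardization at canonical scale is the identity on pixel values", {
  set.seed(31)
  H <- 808
  px <- array(0.02, dim = c(H, H, 3))
  rows <- matrix(0:(H - 1), H, H)
  cols <- t(rows)
  fov <- (rows - (H - 1) / 2)^2 + (cols - (H - 1) / 2)^2 <= 384^2
  tex <- 0.4 + 0.2 * matrix(runif(H * H), H, H)
  for (ch in 1:3) {
    m <- px[, , ch]
    m[fov] <- tex[fov]
    px[, , ch] <- m
  }
  img <- fundus_image(px)
  fv <- detect_fov(img)
  std <- standardize(img, fv)
  expect_lt(abs(std$scale_factor - 1), 1e-3)
  off <- std$crop_offset
  h2 <- dim(std$img$pixels)[1]; w2 <- dim(std$img$pixels)[2]
  expect_identical(std$img$pixels,
                   px[off[1] + (1:h2), off[2] + (1:w2), , drop = FALSE])
})

test_that("red-free filter selects the green channel", {
  red <- array(0, dim = c(64, 64, 3)); red[, , 1] <- 1
  expect_true(all(red_free(fundus_image(red)) == 0))
  green <- array(0, dim = c(64, 64, 3)); green[, , 2] <- 1
  expect_true(all(red_free(fundus_image(green)) == 1))

  sc <- generate_scene(scene_params(seed = 3, n_ma = 1, vessel_count = 0,
                                    noise_sigma = 0, illumination_gradient = 0))
  ma <- sc$truth$lesions[sc$truth$lesions$type == "MA", ]
  g <- red_free(sc$image)
  bg_level <- 0.25 + 0.5 * 0.5  # pigment 0.5
  ctr <- round(c(ma$row, ma$col)) + 1
  expect_equal(g[ctr[1], ctr[2]], bg_level - ma$depth, tolerance = 0.02)
})

test_that("shade correction yields zero darkness on uniform fields and recovers dark dots", {
  u <- matrix(0.6, 128, 128)
  sc <- shade_correct(u)
  expect_true(all(sc$darkness == 0))

  dot <- dip_image(128, 128, c(63.5, 63.5), depth = 0.15, sigma = 2,
                   level = 0.6)
  scd <- shade_correct(dot)
  peak <- max(scd$darkness)
  expect_lt(abs(peak - 0.15), 0.01)
  pk <- which(scd$darkness == peak, arr.ind = TRUE)[1, ]
  expect_lt(max(abs(pk - 1 - c(63.5, 63.5))), 1.5)
})

test_that("bright lesions and the gap between them cannot exceed the candidate depth threshold", {
  m <- matrix(0.5, 160, 160)
  m <- stamp_disc(m, c(79.5, 48), 20, 0.75)
  m <- stamp_disc(m, c(79.5, 71), 20, 0.75)  # ~3-px gap between disc edges
  sc <- shade_correct(m)
  gap <- sc$darkness[70:90, 57:64]
  expect_lt(max(gap), ma_config()$depth_threshold)
})

test_that("darkness is invariant to a global illumination offset", {
  set.seed(11)
  base <- 0.4 + 0.1 * matrix(runif(96 * 96), 96, 96)
  base <- stamp_disc(base, c(47.5, 47.5), 7, 0.25)
  d0 <- shade_correct(base)$darkness
  for (offset in c(0.05, 0.2)) {
    d1 <- shade_correct(base + offset)$darkness
    expect_lt(max(abs(d1 - d0)), 1e-4)
  }
})

test_that("Gaussian enhancement is normalized, exact on constants, and matches brute-force convolution", {
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  expect_equal(sum(enhance(imp)), 1, tolerance = 1e-6)

  const <- matrix(0.3, 40, 40)
  expect_equal(enhance(const), const, tolerance = 1e-12)

  m <- matrix(0, 48, 48)
  m <- stamp_disc(m, c(23.5, 23.5), 7, 0.2)
  expect_lt(max(abs(enhance(m) - conv_gauss_oracle(m, 1))), 1e-9)

  set.seed(4)
  r <- matrix(runif(64 * 64), 64, 64)
  expect_lt(max(abs(enhance(r) - conv_gauss_oracle(r, 1))), 1e-9)
})

test_that("preprocessing satisfies the type invariants and is deterministic", {
  sc <- generate_scene(scene_params(seed = 21, n_ma = 3, n_haem = 1,
                                    n_exudate = 1))
  pre <- preprocess_image(sc$image)
  expect_s3_class(pre, "preprocessed_fundus")
  expect_true(all(pre$darkness >= 0))
  expect_true(all(pre$darkness[pre$intensity >= pre$background] == 0))
  expect_true(all(pre$enhanced >= 0))
  expect_identical(dim(pre$intensity), dim(pre$background))
  expect_identical(dim(pre$intensity), dim(pre$darkness))
  expect_identical(dim(pre$intensity), dim(pre$enhanced))
  expect_identical(dim(pre$intensity), dim(pre$fov$mask))

  pre2 <- preprocess_image(sc$image)
  expect_identical(pre$enhanced, pre2$enhanced)
  expect_identical(pre$darkness, pre2$darkness)

  flat <- disc_image(400, 400, c(199.5, 199.5), 160)
  rej <- preprocess_image(flat)
  expect_s3_class(rej, "fundus_rejection")
  expect_gt(length(rej$report$reasons), 0)
})
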