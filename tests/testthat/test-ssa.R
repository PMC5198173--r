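cfg <- ma_config()

test_that("profile extraction matches closed forms on symmetric and ramp images", {
  # isotropic Gaussian dip (smooth enough that bilinear error stays small):
  # all orientations see the same profile
  x <- dip_image(101, 101, c(50, 50), depth = 0.2, sigma = 9)
  ps <- extract_profiles(x, c(50, 50))
  expect_equal(dim(ps$raw), c(12, 31))
  for (i in 2:12) {
    expect_lt(max(abs(ps$raw[i, ] - ps$raw[1, ])), 1e-3)
  }

  # horizontal ramp: 0 deg profile is linear in the offset, 90 deg constant
  W <- 101
  ramp <- matrix(rep((0:(W - 1)) / (W - 1), each = W), W, W)
  ps <- extract_profiles(ramp, c(50, 50), n_orient = 4)
  expect_equal(ps$orientations, c(0, 45, 90, 135))
  expected0 <- (50 + seq(-15, 15)) / (W - 1)
  expect_equal(ps$raw[1, ], expected0, tolerance = 1e-12)
  vertical <- ps$raw[which(ps$orientations == 90), ]
  expect_lt(max(abs(vertical - 50 / (W - 1))), 1e-12)

  expect_error(extract_profiles(ramp, c(10, 50)), "boundary")
})

test_that("SSA reconstruction has the exact identity and denoising properties", {
  const <- rep(0.4, 31)
  expect_equal(ssa_reconstruct(const, window = 8, n_components = 1), const,
               tolerance = 1e-9)

  set.seed(12)
  prof <- 0.5 + 0.2 * sin(seq(0, 3 * pi, length.out = 31)) + rnorm(31, 0, 0.03)
  expect_equal(ssa_reconstruct(prof, window = 8, n_components = 8), prof,
               tolerance = 1e-9)
  expect_equal(ssa_reconstruct(prof, window = 15, n_components = 15), prof,
               tolerance = 1e-9)

  # leading components recover a noisy sinusoid better than the raw signal
  set.seed(77)
  clean <- sin(seq(0, 2 * pi, length.out = 31))
  noisy <- clean + rnorm(31, 0, 0.05)
  rec <- ssa_reconstruct(noisy, window = 8, n_components = 2)
  rms <- function(e) sqrt(mean(e^2))
  expect_lt(rms(rec - clean), rms(noisy - clean))

  expect_error(ssa_reconstruct(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10), window = 3),
               "non-finite")
})

test_that("symmetry scoring accepts rotationally symmetric dips and rejects anisotropic stamps", {
  # identical non-constant dips: perfect correlation
  t_off <- seq(-15, 15)
  dip <- 1 - 0.2 * exp(-t_off^2 / 8)
  raw <- matrix(rep(dip, 12), nrow = 12, byrow = TRUE)
  ps <- structure(list(center = c(0, 0), diameter = 31,
                       orientations = (0:11) * 15, raw = raw,
                       reconstructed = NULL), class = "profile_set")
  sc <- score_symmetry(ps, cfg)
  expect_equal(sc$min_pair_corr, 1, tolerance = 1e-9)
  expect_true(sc$center_dip)
  expect_true(sc$is_ma)

  # constant profiles: flat region is not a microaneurysm
  flat <- matrix(0.5, 12, 31)
  psf <- structure(list(center = c(0, 0), diameter = 31,
                        orientations = (0:11) * 15, raw = flat,
                        reconstructed = NULL), class = "profile_set")
  scf <- score_symmetry(psf, cfg)
  expect_equal(scf$min_pair_corr, 0)
  expect_false(scf$is_ma)

  # elongated bar (haemorrhage-like): orientation-dependent profiles
  bar <- matrix(0.8, 101, 101)
  bar <- stamp_bar(bar, c(49, 51), c(30, 70), 0.55)
  scb <- score_symmetry(extract_profiles(bar, c(50, 50)), cfg)
  expect_lt(scb$min_pair_corr, cfg$symmetry_threshold)
  expect_false(scb$is_ma)

  # vessel crossing: two crossed bars
  crossing <- matrix(0.8, 101, 101)
  crossing <- stamp_bar(crossing, c(49, 51), c(30, 70), 0.55)
  crossing <- stamp_bar(crossing, c(30, 70), c(49, 51), 0.55)
  scc <- score_symmetry(extract_profiles(crossing, c(50, 50)), cfg)
  expect_false(scc$is_ma)

  # isotropic Gaussian dip through the full scorer: accepted
  x <- dip_image(101, 101, c(50, 50), depth = 0.25, sigma = 2.5)
  scd <- score_symmetry(extract_profiles(x, c(50, 50)), cfg)
  expect_true(scd$is_ma)
  expect_gte(scd$mean_pair_corr, scd$min_pair_corr)
})

test_that("symmetry score is invariant to rotation and affine intensity rescaling", {
  set.seed(5)
  H <- 101
  x <- dip_image(H, H, c(50, 50), depth = 0.25, sigma = 2.5) +
    matrix(rnorm(H * H, 0, 0.005), H, H)
  s1 <- score_symmetry(extract_profiles(x, c(50, 50)), cfg)
  xr <- t(x)[, H:1]  # rotate 90 degrees
  s2 <- score_symmetry(extract_profiles(xr, c(50, 50)), cfg)
  expect_lt(abs(s1$min_pair_corr - s2$min_pair_corr), 0.05)

  ps <- extract_profiles(x, c(50, 50))
  s0 <- score_symmetry(ps, cfg)
  ps_scaled <- ps
  ps_scaled$raw <- 2.5 * ps$raw
  expect_equal(score_symmetry(ps_scaled, cfg)$min_pair_corr, s0$min_pair_corr,
               tolerance = 1e-9)
  ps_affine <- ps
  ps_affine$raw <- 0.7 * ps$raw + 0.2
  expect_lt(abs(score_symmetry(ps_affine, cfg)$min_pair_corr -
                  s0$min_pair_corr), 0.01)
})

test_that("lowering the symmetry threshold never removes confirmed candidates", {
  sc <- generate_scene(scene_params(seed = 88, n_ma = 4, n_haem = 1))
  pre <- preprocess_image(sc$image)
  cand <- detect_candidates(pre)
  counts <- vapply(c(0.95, 0.85, 0.7, 0.5, 0.2), function(th) {
    sum(classify_candidates(pre, cand,
                            ma_config(symmetry_threshold = th))$is_ma)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("classification confirms true microaneurysms and controls image-level false positives", {
  expect_equal(nrow(classify_candidates(
    preprocess_image(generate_scene(scene_params(seed = 2, n_ma = 1))$image),
    data.frame(row = numeric(0), col = numeric(0),
               equivalent_diameter = numeric(0), circularity = numeric(0),
               depth = numeric(0), layer_index = integer(0)))), 0)

  # MA-bearing scenes: matched candidates are overwhelmingly confirmed
  n_matched <- 0; n_true_pos <- 0
  for (s in 1:4) {
    scn <- generate_scene(scene_params(seed = 500 + s, n_ma = 5))
    pre <- preprocess_image(scn$image)
    cls <- classify_candidates(pre, detect_candidates(pre))
    ma <- scn$truth$lesions[scn$truth$lesions$type == "MA", c("row", "col")]
    can <- native_to_canonical(pre, ma)
    for (i in seq_len(nrow(can))) {
      d <- sqrt((cls$row - can[i, 1])^2 + (cls$col - can[i, 2])^2)
      if (any(d <= 3)) {
        n_matched <- n_matched + 1
        if (cls$is_ma[which.min(d)]) n_true_pos <- n_true_pos + 1
      }
    }
  }
  expect_gte(n_true_pos / n_matched, 0.9)

  # MA-free scenes with vessels and haemorrhages: image-level FP rate <= 20%
  fp <- 0
  for (s in 1:50) {
    scn <- generate_scene(scene_params(seed = 700 + s, n_ma = 0, n_haem = 2,
                                       n_exudate = 1))
    res <- detect_image(scn$image)
    if (isTRUE(res$decision$dr_positive)) fp <- fp + 1
  }
  expect_lte(fp / 50, 0.2)
})
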