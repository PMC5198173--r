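cfg <- ma_config()

test_that("layer decomposition is nested and matches direct thresholding", {
  zero <- matrix(0, 32, 32)
  layers <- layer_decompose(zero, config = cfg)
  expect_length(layers, cfg$n_layers)
  expect_true(all(!vapply(layers, any, logical(1))))

  cfg4 <- ma_config(n_layers = 4)
  m <- matrix(0, 64, 64)
  m <- stamp_disc(m, c(31.5, 31.5), 9, 1.0)
  m <- enhance(m, cfg4)
  layers <- layer_decompose(m, config = cfg4)
  expect_length(layers, 4)
  for (t in seq_along(layers)) {
    th <- attr(layers[[t]], "threshold")
    expect_identical(unclass(layers[[t]])[TRUE], (m >= th)[TRUE])
    expect_true(any(layers[[t]]))           # blob present in every layer
    if (t > 1) expect_true(all(layers[[t - 1]][layers[[t]]]))  # nested
  }

  # nestedness holds for arbitrary maps
  set.seed(9)
  r <- enhance(matrix(runif(48 * 48, 0, 0.3), 48, 48), cfg)
  layers <- layer_decompose(r, config = cfg)
  for (t in 2:length(layers)) {
    expect_true(all(layers[[t - 1]][layers[[t]]]))
  }
})

test_that("a 7-px disc yields one candidate; bars and large discs are filtered out", {
  m <- matrix(0, 64, 64)
  m <- stamp_disc(m, c(32, 32), 7, 0.1)
  cand <- candidates_from_enhanced(m, config = cfg)
  expect_equal(nrow(cand), 1)
  expect_lt(max(abs(c(cand$row, cand$col) - 32)), 1)
  expect_gte(cand$equivalent_diameter, 6)
  expect_lte(cand$equivalent_diameter, 8)

  bar <- matrix(0, 72, 72)
  bar <- stamp_bar(bar, c(34, 36), c(16, 55), 0.1)  # 3 x 40 vessel-like bar
  expect_equal(nrow(candidates_from_enhanced(bar, config = cfg)), 0)

  big <- matrix(0, 72, 72)
  big <- stamp_disc(big, c(35.5, 35.5), 25, 0.1)    # haemorrhage-like
  expect_equal(nrow(candidates_from_enhanced(big, config = cfg)), 0)
})

test_that("cross-layer merging keeps one representative from the deepest layer", {
  one <- data.frame(row = 30, col = 30, equivalent_diameter = 7,
                    circularity = 0.8, depth = 0.1, layer_index = 1L)
  expect_identical(merge_candidates(one, cfg), one)

  # nested-threshold blob: same lesion at slightly shifted centroids
  tri <- data.frame(row = c(30, 30.5, 30.2), col = c(30, 30.4, 29.8),
                    equivalent_diameter = c(9, 7, 5),
                    circularity = c(0.7, 0.75, 0.8),
                    depth = c(0.05, 0.08, 0.12), layer_index = 1:3)
  merged <- merge_candidates(tri, cfg)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$layer_index, 3L)

  two <- data.frame(row = c(30, 30), col = c(30, 50),
                    equivalent_diameter = c(7, 7),
                    circularity = c(0.8, 0.8), depth = c(0.1, 0.1),
                    layer_index = c(1L, 1L))
  expect_equal(nrow(merge_candidates(two, cfg)), 2)
})

test_that("candidate extraction equals the exhaustive threshold-and-label oracle", {
  # several small fixtures: isolated discs, a bar, overlapping structures
  fixtures <- list()
  m <- matrix(0, 64, 64)
  m <- stamp_disc(m, c(25, 25), 7, 0.12)
  m <- stamp_disc(m, c(42, 40), 5, 0.2)
  fixtures$two_discs <- enhance(m, cfg)

  m <- matrix(0, 64, 64)
  m <- stamp_bar(m, c(30, 32), c(18, 50), 0.15)
  m <- stamp_disc(m, c(45, 22), 7, 0.1)
  fixtures$bar_and_disc <- enhance(m, cfg)

  set.seed(17)
  m <- matrix(pmax(rnorm(64 * 64, 0, 0.01), 0), 64, 64)
  m <- stamp_disc(m, c(28, 36), 9, 0.18)
  fixtures$noisy <- enhance(m, cfg)

  for (nm in names(fixtures)) {
    got <- sort_candidates(candidates_from_enhanced(fixtures[[nm]], config = cfg))
    want <- sort_candidates(candidate_oracle(fixtures[[nm]], config = cfg))
    expect_equal(nrow(got), nrow(want), info = nm)
    if (nrow(got) > 0) {
      expect_equal(got$row, want$row, tolerance = 1e-9, info = nm)
      expect_equal(got$col, want$col, tolerance = 1e-9, info = nm)
      expect_equal(got$equivalent_diameter, want$equivalent_diameter,
                   tolerance = 1e-9, info = nm)
      expect_equal(got$circularity, want$circularity, tolerance = 1e-9,
                   info = nm)
      expect_equal(got$depth, want$depth, tolerance = 1e-9, info = nm)
      expect_identical(got$layer_index, want$layer_index, info = nm)
    }
  }
})

test_that("candidates are translation-equivariant and monotone in stamp depth", {
  base <- matrix(0, 96, 96)
  for (shift in list(c(0, 0), c(5, 9), c(-7, 4))) {
    m <- stamp_disc(base, c(48, 48) + shift, 7, 0.1)
    cand <- candidates_from_enhanced(enhance(m, cfg), config = cfg)
    expect_equal(nrow(cand), 1)
    expect_lt(abs(cand$row - (48 + shift[1])), 1)
    expect_lt(abs(cand$col - (48 + shift[2])), 1)
  }

  for (depth in c(0.05, 0.1, 0.2, 0.4)) {
    m <- stamp_disc(base, c(48, 48), 7, depth)
    cand <- candidates_from_enhanced(enhance(m, cfg), config = cfg)
    expect_equal(nrow(cand), 1, info = paste("depth", depth))
  }
})

test_that("the candidate stage catches essentially every true microaneurysm", {
  n_matched <- 0; n_true <- 0
  for (s in 1:4) {
    sc <- generate_scene(scene_params(seed = 400 + s, n_ma = 5, n_haem = 1))
    pre <- preprocess_image(sc$image)
    cand <- detect_candidates(pre)
    ma <- sc$truth$lesions[sc$truth$lesions$type == "MA", c("row", "col")]
    can <- native_to_canonical(pre, ma)
    for (i in seq_len(nrow(can))) {
      n_true <- n_true + 1
      d <- sqrt((cand$row - can[i, 1])^2 + (cand$col - can[i, 2])^2)
      if (any(d <= 3)) n_matched <- n_matched + 1
    }
  }
  expect_gte(n_matched / n_true, 0.95)

  # blank scene: no candidates at all
  blank <- generate_scene(scene_params(seed = 5, vessel_count = 0,
                                       n_haem = 0, n_exudate = 0,
                                       noise_sigma = 0))
  pre <- preprocess_image(blank$image)
  # flat scenes fail the vessel-contrast gate, so work from the maps directly
  if (inherits(pre, "fundus_rejection")) {
    sc2 <- shade_correct(red_free(blank$image), detect_fov(blank$image))
    cand <- candidates_from_enhanced(enhance(sc2$darkness),
                                     detect_fov(blank$image), cfg)
  } else {
    cand <- detect_candidates(pre)
  }
  expect_equal(nrow(cand), 0)
})
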