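#' Synthetic fundus scene parameters
#'
#' Parameters of the synthetic fovea-centred fundus generator. The generator
#' emulates the background variability that makes automated detection hard:
#' pigmentation level (mapped linearly to background green intensity in
#' `[0.25, 0.75]` — an explicit, crude proxy), uneven illumination, a
#' branching vessel tree of varying calibre, dark elongated haemorrhages,
#' bright exudates, and microaneurysms as isotropic Gaussian dips. The
#' default frame puts the field of view at the pipeline's canonical scale
#' (768-px diameter), where a typical microaneurysm is ~7 px across.
#'
#' @param seed Integer RNG seed; scenes are bit-reproducible given the seed.
#' @param frame `c(H, W)` frame size in px.
#' @param fov_radius Field-of-view radius in px.
#' @param pigment_level Background pigmentation proxy in `[0, 1]`.
#' @param illumination_gradient Relative amplitude of the linear illumination
#'   gradient across the field.
#' @param vessel_count Number of primary vessels.
#' @param vessel_width_range Vessel width range `c(min, max)` in px.
#' @param vessel_depth_range Green-channel depth range of vessels.
#' @param n_ma Number of microaneurysm stamps.
#' @param ma_diameter_range Microaneurysm diameter range in px.
#' @param ma_depth_range Microaneurysm green-channel dip depth range.
#' @param n_haem Number of haemorrhage stamps (flat-topped elongated blots,
#'   aspect ratio 3-4.5).
#' @param n_exudate Number of bright exudate stamps.
#' @param noise_sigma Gaussian pixel-noise standard deviation.
#' @return A list of class `"scene_params"`.
#' @export
scene_params <- function(seed,
                         frame = c(808, 808),
                         fov_radius = 384,
                         pigment_level = 0.5,
                         illumination_gradient = 0.15,
                         vessel_count = 7,
                         vessel_width_range = c(3, 7),
                         vessel_depth_range = c(0.08, 0.14),
                         n_ma = 0,
                         ma_diameter_range = c(5, 9),
                         ma_depth_range = c(0.08, 0.18),
                         n_haem = 0,
                         n_exudate = 0,
                         noise_sigma = 0.01) {
  stopifnot(length(frame) == 2,
            fov_radius + 16 <= min(frame) / 2,
            pigment_level >= 0, pigment_level <= 1,
            diff(vessel_width_range) >= 0, diff(vessel_depth_range) >= 0,
            n_ma >= 0, diff(ma_diameter_range) >= 0,
            diff(ma_depth_range) >= 0,
            n_haem >= 0, n_exudate >= 0, noise_sigma >= 0)
  structure(as.list(environment()), class = "scene_params")
}

# Stamp filled discs of given radii at the given (0-based) points into `mat`
# using pmax-combination with `value`; indices outside the frame are dropped.
stamp_discs <- function(mat, rows, cols, radii, value) {
  H <- nrow(mat); W <- ncol(mat)
  for (rad in sort(unique(pmax(1L, as.integer(round(radii)))))) {
    sel <- pmax(1L, as.integer(round(radii))) == rad
    off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
    rr <- rep(as.integer(round(rows[sel])), each = nrow(off)) + off$dr + 1L
    cc <- rep(as.integer(round(cols[sel])), each = nrow(off)) + off$dc + 1L
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx <- cbind(rr[ok], cc[ok])
    mat[idx] <- pmax(mat[idx], value)
  }
  mat
}

# Flat-topped (supergaussian) elliptical dip with pmax-combination: blot
# haemorrhages have fairly uniform density with defined edges, unlike the
# smooth Gaussian profile of a microaneurysm.
stamp_blot <- function(mat, row, col, a, b, angle, depth) {
  H <- nrow(mat); W <- ncol(mat)
  ext <- ceiling(2 * a)
  r0 <- max(1, round(row) - ext + 1); r1 <- min(H, round(row) + ext + 1)
  c0 <- max(1, round(col) - ext + 1); c1 <- min(W, round(col) + ext + 1)
  rr <- (r0:r1) - 1 - row
  cc <- (c0:c1) - 1 - col
  u <- outer(rr, cc, function(p, q) p * sin(angle) + q * cos(angle))
  v <- outer(rr, cc, function(p, q) p * cos(angle) - q * sin(angle))
  qq <- (u / a)^2 + (v / b)^2
  dip <- depth * exp(-qq^2 / 2)
  mat[r0:r1, c0:c1] <- pmax(mat[r0:r1, c0:c1], dip)
  mat
}

# Anisotropic Gaussian dip stamped into a local window with pmax-combination.
stamp_gaussian <- function(mat, row, col, sig_major, sig_minor, angle, depth) {
  H <- nrow(mat); W <- ncol(mat)
  ext <- ceiling(3.2 * sig_major)
  r0 <- max(1, round(row) - ext + 1); r1 <- min(H, round(row) + ext + 1)
  c0 <- max(1, round(col) - ext + 1); c1 <- min(W, round(col) + ext + 1)
  rr <- (r0:r1) - 1 - row
  cc <- (c0:c1) - 1 - col
  u <- outer(rr, cc, function(a, b) a * sin(angle) + b * cos(angle))
  v <- outer(rr, cc, function(a, b) a * cos(angle) - b * sin(angle))
  dip <- depth * exp(-0.5 * ((u / sig_major)^2 + (v / sig_minor)^2))
  mat[r0:r1, c0:c1] <- pmax(mat[r0:r1, c0:c1], dip)
  mat
}

#' Generate a synthetic fundus scene with ground truth
#'
#' Renders, in order: pigmented background with illumination gradient, a
#' random-walk vessel tree with tapering width, elongated haemorrhages,
#' bright exudates, microaneurysm stamps (placed at least 20 px away from
#' vessels and every other lesion, so ground-truth matching within a 3-px
#' radius is unambiguous), and Gaussian pixel noise. Deterministic given
#' `p$seed`; the caller's RNG state is left untouched.
#'
#' @param p A [scene_params()].
#' @return A list with `image` (a [fundus_image()]) and `truth` (a list of
#'   class `"ground_truth"` with `lesions` data frame — `type`, `row`, `col`
#'   0-based, `diameter`, `depth` — and `has_ma`).
#' @export
generate_scene <- function(p) {
  stopifnot(inherits(p, "scene_params"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(p$seed)

  H <- p$frame[1]; W <- p$frame[2]
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d2 <- (rows - ctr[1])^2 + (cols - ctr[2])^2
  fov <- d2 <= p$fov_radius^2

  # background: pigmented green level + linear illumination gradient
  g0 <- 0.25 + 0.5 * p$pigment_level
  phi <- runif(1, 0, 2 * pi)
  u <- (cols - ctr[2]) / p$fov_radius
  v <- (rows - ctr[1]) / p$fov_radius
  green <- g0 * (1 + p$illumination_gradient * (u * cos(phi) + v * sin(phi)))

  # vessel tree: random-walk segments radiating from near the centre,
  # width tapering outward, pmax-combined depth map
  vdepth <- matrix(0, H, W)
  if (p$vessel_count > 0) {
    for (k in seq_len(p$vessel_count)) {
      w0 <- runif(1, p$vessel_width_range[1], p$vessel_width_range[2])
      dep <- runif(1, p$vessel_depth_range[1], p$vessel_depth_range[2])
      heading0 <- 2 * pi * (k - 1) / p$vessel_count + runif(1, -0.3, 0.3)
      n_steps <- floor(0.95 * p$fov_radius / 2)
      headings <- heading0 + cumsum(rnorm(n_steps, 0, 0.1))
      pr <- ctr[1] + cumsum(2 * sin(headings)) + runif(1, -10, 10)
      pc <- ctr[2] + cumsum(2 * cos(headings)) + runif(1, -10, 10)
      keep <- (pr - ctr[1])^2 + (pc - ctr[2])^2 <= (0.97 * p$fov_radius)^2
      if (!any(keep)) next
      widths <- seq(w0, max(1, 0.4 * w0), length.out = n_steps)[keep]
      vdepth <- stamp_discs(vdepth, pr[keep], pc[keep], widths / 2, dep)
    }
    vdepth <- cpp_gaussian_blur(vdepth, 0.8)
  }
  occupied <- vdepth > 0.01

  lesions <- data.frame(type = character(0), row = numeric(0),
                        col = numeric(0), diameter = numeric(0),
                        depth = numeric(0))

  # 20-px clearance check against already-rendered structure and lesions
  clear_of <- function(row, col, margin = 20) {
    r0 <- max(1, round(row) - margin + 1); r1 <- min(H, round(row) + margin + 1)
    c0 <- max(1, round(col) - margin + 1); c1 <- min(W, round(col) + margin + 1)
    if (any(occupied[r0:r1, c0:c1])) return(FALSE)
    if (nrow(lesions) > 0) {
      dd <- sqrt((lesions$row - row)^2 + (lesions$col - col)^2)
      if (any(dd < margin)) return(FALSE)
    }
    TRUE
  }
  place <- function(max_r) {
    for (i in seq_len(1000)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- max_r * sqrt(runif(1))
      row <- ctr[1] + rad * sin(ang)
      col <- ctr[2] + rad * cos(ang)
      if (clear_of(row, col)) return(c(row, col))
    }
    stop("lesion placement failed after 1000 attempts (overcrowded scene)")
  }

  hdepth <- matrix(0, H, W)
  if (p$n_haem > 0) {
    for (k in seq_len(p$n_haem)) {
      pos <- place(p$fov_radius - 80)
      a <- runif(1, 6, 12)
      aspect <- runif(1, 3, 4.5)
      dep <- runif(1, 0.10, 0.18)
      hdepth <- stamp_blot(hdepth, pos[1], pos[2], a, a / aspect,
                           runif(1, 0, pi), dep)
      lesions <- rbind(lesions, data.frame(
        type = "haemorrhage", row = pos[1], col = pos[2],
        diameter = 3 * a, depth = dep))
      occupied <- occupied | hdepth > 0.02
    }
  }

  bright <- matrix(0, H, W)
  if (p$n_exudate > 0) {
    for (k in seq_len(p$n_exudate)) {
      pos <- place(p$fov_radius - 60)
      rad <- runif(1, 4, 10)
      amp <- runif(1, 0.10, 0.20)
      ext <- ceiling(2 * rad)
      r0 <- max(1, round(pos[1]) - ext + 1); r1 <- min(H, round(pos[1]) + ext + 1)
      c0 <- max(1, round(pos[2]) - ext + 1); c1 <- min(W, round(pos[2]) + ext + 1)
      dd <- outer(((r0:r1) - 1 - pos[1])^2, ((c0:c1) - 1 - pos[2])^2, "+")
      bright[r0:r1, c0:c1] <- pmax(bright[r0:r1, c0:c1],
                                   amp * exp(-(dd / rad^2)^2))
      lesions <- rbind(lesions, data.frame(
        type = "exudate", row = pos[1], col = pos[2],
        diameter = 2 * rad, depth = -amp))
      occupied <- occupied | bright > 0.02
    }
  }

  madepth <- matrix(0, H, W)
  if (p$n_ma > 0) {
    for (k in seq_len(p$n_ma)) {
      pos <- place(p$fov_radius - 64)
      dia <- runif(1, p$ma_diameter_range[1], p$ma_diameter_range[2])
      dep <- runif(1, p$ma_depth_range[1], p$ma_depth_range[2])
      madepth <- stamp_gaussian(madepth, pos[1], pos[2], dia / 4, dia / 4,
                                0, dep)
      lesions <- rbind(lesions, data.frame(
        type = "MA", row = pos[1], col = pos[2], diameter = dia, depth = dep))
    }
  }

  green <- green - vdepth - hdepth - madepth + bright
  red <- green * 0.5 + 0.42 + 0.12 * p$pigment_level
  blue <- green * 0.4
  surround <- !fov
  red[surround] <- 0.02
  green[surround] <- 0.02
  blue[surround] <- 0.02
  px <- array(c(red, green, blue), dim = c(H, W, 3))
  if (p$noise_sigma > 0) {
    px <- px + rnorm(length(px), 0, p$noise_sigma)
  }
  px[px < 0] <- 0
  px[px > 1] <- 1

  truth <- structure(list(lesions = lesions,
                          has_ma = any(lesions$type == "MA")),
                     class = "ground_truth")
  list(image = fundus_image(px, image_id = sprintf("synthetic_%d", p$seed),
                            cohort = "synthetic"),
       truth = truth)
}

#' Cohort specification
#'
#' @param name Cohort name.
#' @param n_images Number of images.
#' @param ma_prevalence Fraction of images containing at least one
#'   microaneurysm; realized as the exact deterministic count
#'   `round(n_images * ma_prevalence)` (not binomial sampling), so
#'   cohort-level statistics carry no Monte-Carlo noise.
#' @param pigment_level Background pigmentation proxy shared by all scenes.
#' @param seed Cohort seed; drives image order, per-image seeds and lesion
#'   draws.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(name, n_images, ma_prevalence, pigment_level, seed) {
  stopifnot(n_images >= 1, ma_prevalence >= 0, ma_prevalence <= 1,
            pigment_level >= 0, pigment_level <= 1)
  structure(list(name = name, n_images = as.integer(n_images),
                 ma_prevalence = ma_prevalence,
                 pigment_level = pigment_level, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Deterministic cohort plan
#'
#' Lays out a cohort without rendering any pixels: exactly
#' `round(n_images * ma_prevalence)` images are assigned `has_ma = TRUE` (in
#' a seed-shuffled order), and every image receives its own scene seed and
#' lesion counts. [generate_cohort()] materializes this plan.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `image_id`, `cohort`, `scene_seed`,
#'   `has_ma`, `n_ma`, `n_haem`, `n_exudate`, `pigment_level`.
#' @export
cohort_plan <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  n <- spec$n_images
  n_pos <- round(n * spec$ma_prevalence)
  pos <- logical(n)
  pos[sample.int(n, n_pos)] <- TRUE
  data.frame(
    image_id = sprintf("%s_%04d", spec$name, seq_len(n)),
    cohort = spec$name,
    scene_seed = (spec$seed %% 100000L) * 10000L + seq_len(n),
    has_ma = pos,
    n_ma = ifelse(pos, sample(1:6, n, replace = TRUE), 0L),
    n_haem = sample(0:2, n, replace = TRUE),
    n_exudate = sample(0:2, n, replace = TRUE),
    pigment_level = spec$pigment_level
  )
}

# Scene parameters for one row of a cohort plan.
plan_scene_params <- function(plan_row, ...) {
  scene_params(seed = plan_row$scene_seed,
               pigment_level = plan_row$pigment_level,
               n_ma = plan_row$n_ma,
               n_haem = plan_row$n_haem,
               n_exudate = plan_row$n_exudate,
               ...)
}

#' Generate a full synthetic cohort
#'
#' Materializes [cohort_plan()] into rendered scenes. For large cohorts this
#' holds every frame in memory; prefer iterating over the plan and calling
#' [generate_scene()] per image when only streaming access is needed.
#'
#' @param spec A [cohort_spec()].
#' @param ... Additional [scene_params()] overrides applied to every scene.
#' @return A list of `list(image, truth)` pairs, one per image, with
#'   `image$image_id` and `image$cohort` taken from the plan.
#' @export
generate_cohort <- function(spec, ...) {
  plan <- cohort_plan(spec)
  lapply(seq_len(nrow(plan)), function(i) {
    sc <- generate_scene(plan_scene_params(plan[i, ], ...))
    sc$image$image_id <- plan$image_id[i]
    sc$image$cohort <- plan$cohort[i]
    sc
  })
}

#' Six-cohort preset
#'
#' Returns six cohort specifications named after the screening datasets of a
#' published six-country evaluation (Kenya, Botswana, Norway, Mongolia,
#' China, UK) with their reported microaneurysm prevalences (9.2%, 30.4%,
#' 9.6%, 11.3%, 8.2%, 11.7%) and six distinct pigmentation levels spanning
#' `[0.2, 0.8]`, strictly increasing across the preset order. Each cohort
#' gets a distinct seed, so image-id spaces are disjoint.
#'
#' @param n_images Images per cohort. Default 100 (desk scale).
#' @param seed_base Base seed; cohort `i` uses `seed_base + 1000 * i`.
#' @return A list of six [cohort_spec()] objects.
#' @export
six_cohort_preset <- function(n_images = 100, seed_base = 20160L) {
  names <- c("Kenya", "Botswana", "Norway", "Mongolia", "China", "UK")
  prevalence <- c(0.092, 0.304, 0.096, 0.113, 0.082, 0.117)
  pigment <- seq(0.2, 0.8, length.out = 6)
  lapply(seq_along(names), function(i) {
    cohort_spec(names[i], n_images, prevalence[i], pigment[i],
                seed_base + 1000L * i)
  })
}
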