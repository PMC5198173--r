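#' Detect the retinal field of view
#'
#' Fundus photographs show the illuminated circular retina on a dark
#' surround. The field of view (FOV) is taken as the largest connected
#' bright region; its circle fit uses the region centroid and the
#' area-equivalent radius.
#'
#' @param img A [fundus_image()].
#' @param config An [ma_config()].
#' @return A list of class `"fov_mask"` with `mask` (logical `H x W`),
#'   `center` (0-based `c(row, col)`) and `radius` (px).
#' @export
detect_fov <- function(img, config = ma_config()) {
  stopifnot(inherits(img, "fundus_image"))
  lum <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / 3
  bright <- lum > config$fov_threshold
  if (mean(bright) < 0.2) {
    stop("no field of view: fewer than 20% of pixels above the surround threshold")
  }
  lab <- cpp_label8(bright)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  frac <- mean(mask)
  if (frac <= 0.2) {
    stop("no field of view: largest bright region covers too little of the frame")
  }
  if (frac >= 0.95) {
    stop("no field of view: bright region covers nearly the whole frame (no dark surround)")
  }
  idx <- which(mask, arr.ind = TRUE)
  center <- c(mean(idx[, 1]), mean(idx[, 2])) - 1  # 0-based
  radius <- sqrt(sum(mask) / pi)
  structure(list(mask = mask, center = center, radius = radius),
            class = "fov_mask")
}

#' Assess image quality for grading
#'
#' An image is gradable when the retinal vasculature is visible, the field of
#' view fills a plausible fraction of the frame, and it is roughly centred in
#' the frame. Vasculature visibility is measured as the 95th percentile of
#' the gradient magnitude of the lightly smoothed green channel inside the
#' field (x100): vessel edges dominate this statistic when vessels are
#' resolvable, while smoothing keeps pixel noise from inflating it.
#'
#' @inheritParams detect_fov
#' @param fov A `"fov_mask"` from [detect_fov()].
#' @return A list of class `"quality_report"` with `gradable`,
#'   `vessel_contrast`, `fov_fraction` and `reasons`.
#' @export
assess_quality <- function(img, fov, config = ma_config()) {
  stopifnot(inherits(img, "fundus_image"), inherits(fov, "fov_mask"))
  g <- cpp_gaussian_blur(img$pixels[, , 2], 2)
  H <- nrow(g); W <- ncol(g)
  # central-difference gradient magnitude on the smoothed green channel
  gr <- matrix(0, H, W); gc <- matrix(0, H, W)
  gr[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  gc[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  gm <- sqrt(gr^2 + gc^2)
  # evaluate inside the field, away from its rim (the rim itself is an edge)
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d2 <- (rows - fov$center[1])^2 + (cols - fov$center[2])^2
  interior <- fov$mask & (d2 <= (0.9 * fov$radius)^2)
  vessel_contrast <- if (any(interior)) {
    100 * quantile(gm[interior], 0.95, names = FALSE)
  } else 0
  fov_fraction <- mean(fov$mask)

  reasons <- character(0)
  if (vessel_contrast < config$quality_min_contrast) {
    reasons <- c(reasons, "low vessel contrast")
  }
  if (fov_fraction < config$fov_fraction_bounds[1] ||
      fov_fraction > config$fov_fraction_bounds[2]) {
    reasons <- c(reasons, "field of view fraction out of bounds")
  }
  off <- sqrt(sum((fov$center - c((H - 1) / 2, (W - 1) / 2))^2))
  if (off > config$center_tolerance * sqrt(H^2 + W^2)) {
    reasons <- c(reasons, "field of view not centred")
  }
  structure(list(gradable = length(reasons) == 0,
                 vessel_contrast = vessel_contrast,
                 fov_fraction = fov_fraction,
                 reasons = reasons),
            class = "quality_report")
}

#' Standardize an image to the canonical scale
#'
#' Crops to the field-of-view bounding box plus a margin and rescales
#' (bilinear) so the field-of-view diameter equals
#' `config$canonical_diameter`. When the measured scale factor is within
#' 1e-3 of 1, resampling is skipped and pixels pass through unchanged.
#'
#' @inheritParams assess_quality
#' @return A list with `img` (standardized [fundus_image()]), `fov` (its
#'   `"fov_mask"`), `scale_factor` (canonical px per native px) and
#'   `crop_offset` (0-based `c(row, col)` of the crop origin in the native
#'   frame, so `native = canonical / scale_factor + crop_offset`).
#' @export
standardize <- function(img, fov, config = ma_config()) {
  stopifnot(inherits(img, "fundus_image"), inherits(fov, "fov_mask"))
  if (fov$radius < config$min_fov_radius) {
    stop("field of view too small to standardize (radius < ",
         config$min_fov_radius, " px)")
  }
  H <- nrow(fov$mask); W <- ncol(fov$mask)
  idx <- which(fov$mask, arr.ind = TRUE)
  m <- config$crop_margin
  r0 <- max(1, min(idx[, 1]) - m); r1 <- min(H, max(idx[, 1]) + m)
  c0 <- max(1, min(idx[, 2]) - m); c1 <- min(W, max(idx[, 2]) + m)
  px <- img$pixels[r0:r1, c0:c1, , drop = FALSE]
  msk <- fov$mask[r0:r1, c0:c1]
  scale <- config$canonical_diameter / (2 * fov$radius)
  if (abs(scale - 1) >= 1e-3) {
    newH <- max(64L, as.integer(round(nrow(msk) * scale)))
    newW <- max(64L, as.integer(round(ncol(msk) * scale)))
    px <- vapply(1:3, function(ch) cpp_resize_bilinear(px[, , ch], newH, newW),
                 matrix(0, newH, newW))
    px[px < 0] <- 0
    px[px > 1] <- 1
    msk <- cpp_resize_bilinear(msk + 0, newH, newW) > 0.5
  }
  idx2 <- which(msk, arr.ind = TRUE)
  new_fov <- structure(
    list(mask = msk,
         center = c(mean(idx2[, 1]), mean(idx2[, 2])) - 1,
         radius = sqrt(sum(msk) / pi)),
    class = "fov_mask")
  list(img = fundus_image(px, image_id = img$image_id, cohort = img$cohort),
       fov = new_fov, scale_factor = scale, crop_offset = c(r0 - 1, c0 - 1))
}

#' Map native-frame coordinates to the canonical frame
#'
#' Converts 0-based `(row, col)` positions in the original photograph to the
#' cropped, rescaled canonical frame of a preprocessed image (or back with
#' [canonical_to_native()]). Useful for matching ground-truth annotations to
#' detected candidates.
#'
#' @param pre A `"preprocessed_fundus"` (or any list with `scale_factor` and
#'   `crop_offset`).
#' @param rc Two-column matrix or data frame of 0-based `(row, col)`.
#' @return Matrix of transformed 0-based `(row, col)`.
#' @export
native_to_canonical <- function(pre, rc) {
  rc <- as.matrix(rc)
  cbind((rc[, 1] - pre$crop_offset[1]) * pre$scale_factor,
        (rc[, 2] - pre$crop_offset[2]) * pre$scale_factor)
}

#' @rdname native_to_canonical
#' @export
canonical_to_native <- function(pre, rc) {
  rc <- as.matrix(rc)
  cbind(rc[, 1] / pre$scale_factor + pre$crop_offset[1],
        rc[, 2] / pre$scale_factor + pre$crop_offset[2])
}

#' Red-free intensity
#'
#' The red-free view of a fundus photograph is its green channel: blood-borne
#' structures (vessels, microaneurysms, haemorrhages) absorb green light and
#' appear dark with maximal contrast.
#'
#' @param img A [fundus_image()].
#' @return `H x W` intensity matrix in `[0, 1]`.
#' @export
red_free <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  img$pixels[, , 2]
}

#' Shade correction
#'
#' Estimates a smooth background as a running median (square window of side
#' `config$background_window`) of the red-free intensity and returns the
#' clipped darkness map `max(background - intensity, 0)`. Dark lesions become
#' positive blobs; pixels at or above the background — including exudates and
#' cotton-wool spots — clip to zero, so bright lesions and the narrow gaps
#' between adjacent bright lesions cannot masquerade as dark lesions. Before
#' filtering, the dark surround outside the field of view is filled by
#' radially extending the intensity at the field rim, so the background
#' estimate stays faithful near the rim even under an illumination gradient;
#' frame edges are mirrored.
#'
#' @param intensity `H x W` red-free intensity at canonical scale.
#' @param fov A `"fov_mask"` (optional; `NULL` treats the whole frame as
#'   field).
#' @param config An [ma_config()].
#' @return A list with `background` and `darkness` matrices.
#' @export
shade_correct <- function(intensity, fov = NULL, config = ma_config()) {
  stopifnot(is.matrix(intensity))
  x <- intensity
  if (!is.null(fov)) {
    stopifnot(inherits(fov, "fov_mask"))
    out <- which(!fov$mask)
    if (length(out) > 0) {
      H <- nrow(x); W <- ncol(x)
      r0 <- (out - 1) %% H
      c0 <- (out - 1) %/% H
      dr <- r0 - fov$center[1]
      dc <- c0 - fov$center[2]
      rad <- pmax(sqrt(dr^2 + dc^2), 1e-9)
      s <- pmin(1, (fov$radius - 2) / rad)
      rr <- pmin(pmax(fov$center[1] + dr * s, 0), H - 1)
      cc <- pmin(pmax(fov$center[2] + dc * s, 0), W - 1)
      x[out] <- cpp_bilinear(intensity, rr, cc)
    }
  }
  background <- cpp_median_filter(x, (config$background_window - 1L) %/% 2L)
  darkness <- pmax(background - intensity, 0)
  if (!is.null(fov)) darkness[!fov$mask] <- 0
  list(background = background, darkness = darkness)
}

#' Enhance small dark structures
#'
#' Gaussian smoothing (sd `config$enhance_sigma` px, symmetric boundary) of
#' the darkness map; matched to the few-pixel scale of microaneurysms, it
#' raises their contrast against pixel noise while preserving total mass of
#' interior structures.
#'
#' @param darkness Nonnegative `H x W` matrix.
#' @param config An [ma_config()].
#' @return Smoothed `H x W` matrix.
#' @export
enhance <- function(darkness, config = ma_config()) {
  stopifnot(is.matrix(darkness), min(darkness) >= 0)
  cpp_gaussian_blur(darkness, config$enhance_sigma)
}

#' Preprocess a fundus photograph
#'
#' Runs the full preprocessing stage: field-of-view detection, quality gate,
#' standardization to canonical scale, red-free filtering, shade correction
#' and small-structure enhancement. Ungradable images are rejected (the
#' quality report is returned instead of maps).
#'
#' @param img A [fundus_image()].
#' @param config An [ma_config()].
#' @return An object of class `"preprocessed_fundus"` with fields
#'   `image_id`, `cohort`, `intensity`, `background`, `darkness`, `enhanced`,
#'   `fov`, `scale_factor` and `quality`; or an object of class
#'   `"fundus_rejection"` carrying `image_id`, `cohort` and `report` when the
#'   image fails the quality gate.
#' @export
preprocess_image <- function(img, config = ma_config()) {
  fov <- detect_fov(img, config)
  quality <- assess_quality(img, fov, config)
  if (!quality$gradable) {
    return(structure(list(image_id = img$image_id, cohort = img$cohort,
                          report = quality),
                     class = "fundus_rejection"))
  }
  std <- standardize(img, fov, config)
  intensity <- red_free(std$img)
  sc <- shade_correct(intensity, std$fov, config)
  enhanced <- enhance(sc$darkness, config)
  structure(
    list(image_id = img$image_id, cohort = img$cohort,
         intensity = intensity, background = sc$background,
         darkness = sc$darkness, enhanced = enhanced,
         fov = std$fov, scale_factor = std$scale_factor,
         crop_offset = std$crop_offset, quality = quality),
    class = "preprocessed_fundus")
}

#' @export
print.preprocessed_fundus <- function(x, ...) {
  cat(sprintf("<preprocessed_fundus> %s [%s] %d x %d px (scale %.3f)\n",
              x$image_id, x$cohort, nrow(x$intensity), ncol(x$intensity),
              x$scale_factor))
  invisible(x)
}

#' @export
print.fundus_rejection <- function(x, ...) {
  cat(sprintf("<fundus_rejection> %s [%s]: %s\n", x$image_id, x$cohort,
              paste(x$report$reasons, collapse = "; ")))
  invisible(x)
}
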