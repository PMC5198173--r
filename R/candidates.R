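#' Decompose the enhanced darkness map into nested threshold layers
#'
#' Layer `t` is the binary map `enhanced >= theta_t` for thresholds
#' `theta_1 < ... < theta_K` evenly spaced between the candidate depth
#' threshold `tau_d` and the 99.9th percentile of the enhanced map inside the
#' field of view. Layers are nested by construction: each deeper layer is a
#' subset of the previous one. A map that never reaches `tau_d` yields empty
#' layers.
#'
#' @param enhanced Nonnegative `H x W` matrix.
#' @param fov A `"fov_mask"` or `NULL` (whole frame).
#' @param config An [ma_config()]; uses `n_layers` and `depth_threshold`.
#' @return A list of `n_layers` logical matrices, shallowest first, with the
#'   threshold attached as attribute `"threshold"`.
#' @export
layer_decompose <- function(enhanced, fov = NULL, config = ma_config()) {
  stopifnot(is.matrix(enhanced), min(enhanced) >= 0)
  inside <- if (is.null(fov)) enhanced else enhanced[fov$mask]
  top <- quantile(inside, 0.999, names = FALSE)
  tau <- config$depth_threshold
  thresholds <- seq(tau, max(top, tau), length.out = config$n_layers)
  lapply(thresholds, function(th) {
    m <- enhanced >= th
    if (!is.null(fov)) m <- m & fov$mask
    attr(m, "threshold") <- th
    m
  })
}

# Distance-from-field-edge test: centroid must be >= margin px from both the
# field-of-view rim (analytic, circular fit) and the frame edges.
inside_eroded_fov <- function(row, col, fov, margin, H, W) {
  ok_frame <- row >= margin & row <= H - 1 - margin &
    col >= margin & col <= W - 1 - margin
  if (is.null(fov)) return(ok_frame)
  d <- sqrt((row - fov$center[1])^2 + (col - fov$center[2])^2)
  ok_frame & (d <= fov$radius - margin)
}

#' Extract candidate lesions from one threshold layer
#'
#' Labels 8-connected components of the layer and keeps those that look like
#' microaneurysms: equivalent diameter (`2*sqrt(area/pi)`) within
#' `config$diameter_range`, circularity (`4*pi*area/perimeter^2`, perimeter
#' counted as exposed 4-neighbour pixel edges) at least
#' `config$min_circularity`, mean enhanced darkness at least
#' `config$depth_threshold`, and centroid inside the field of view eroded by
#' `config$border_margin` px. Centroids are intensity-weighted (by the
#' enhanced map) and 0-based.
#'
#' @param layer Logical `H x W` matrix (one layer).
#' @param enhanced The enhanced darkness map the layers were cut from.
#' @param fov A `"fov_mask"` or `NULL`.
#' @param config An [ma_config()].
#' @param layer_index Integer tag stored with each candidate.
#' @return A data frame with columns `row`, `col` (0-based centroid),
#'   `equivalent_diameter`, `circularity`, `depth`, `layer_index`.
#' @export
extract_layer_candidates <- function(layer, enhanced, fov = NULL,
                                     config = ma_config(), layer_index = 0L) {
  stopifnot(is.matrix(layer), is.matrix(enhanced))
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      equivalent_diameter = numeric(0),
                      circularity = numeric(0), depth = numeric(0),
                      layer_index = integer(0))
  if (!any(layer)) return(empty)
  lab <- cpp_label8(layer)
  st <- cpp_component_stats(lab, enhanced)
  area <- st[, 1]; perim <- st[, 2]
  eq_diam <- 2 * sqrt(area / pi)
  circ <- 4 * pi * area / perim^2
  depth <- st[, 3] / area
  wr <- ifelse(st[, 3] > 0, st[, 4] / st[, 3], st[, 6] / area)
  wc <- ifelse(st[, 3] > 0, st[, 5] / st[, 3], st[, 7] / area)
  keep <- eq_diam >= config$diameter_range[1] &
    eq_diam <= config$diameter_range[2] &
    circ >= config$min_circularity &
    depth >= config$depth_threshold &
    inside_eroded_fov(wr, wc, fov, config$border_margin,
                      nrow(layer), ncol(layer))
  if (!any(keep)) return(empty)
  data.frame(row = wr[keep], col = wc[keep],
             equivalent_diameter = eq_diam[keep],
             circularity = circ[keep], depth = depth[keep],
             layer_index = as.integer(layer_index))
}

#' Merge candidates found in multiple layers
#'
#' The same lesion is typically found in several nested layers. Candidates
#' whose centroids lie within `config$merge_radius` px of a retained
#' representative are dropped; representatives are chosen greedily, deepest
#' layer first, ties broken by larger depth, then by lexicographic centroid.
#'
#' @param candidates Data frame of per-layer candidates (rows from
#'   [extract_layer_candidates()]).
#' @param config An [ma_config()].
#' @return The merged candidate data frame.
#' @export
merge_candidates <- function(candidates, config = ma_config()) {
  if (nrow(candidates) <= 1) return(candidates)
  ord <- order(-candidates$layer_index, -candidates$depth,
               candidates$row, candidates$col)
  cand <- candidates[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    taken <- which(keep)
    if (length(taken) == 0) {
      keep[i] <- TRUE
      next
    }
    d <- sqrt((cand$row[taken] - cand$row[i])^2 +
                (cand$col[taken] - cand$col[i])^2)
    keep[i] <- all(d > config$merge_radius)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect all potential microaneurysm candidates
#'
#' Stage two of the pipeline: multilayered dark-object filtering of the
#' enhanced darkness map, tuned to lesions approximately seven pixels in
#' diameter at canonical scale. This stage is deliberately permissive — it
#' must catch essentially every true microaneurysm, accepting false
#' candidates that the symmetry classifier removes later.
#'
#' @param pre A `"preprocessed_fundus"` from [preprocess_image()].
#' @param config An [ma_config()].
#' @return Candidate data frame (see [extract_layer_candidates()]), merged
#'   across layers.
#' @export
detect_candidates <- function(pre, config = ma_config()) {
  stopifnot(inherits(pre, "preprocessed_fundus"))
  layers <- layer_decompose(pre$enhanced, pre$fov, config)
  per_layer <- lapply(seq_along(layers), function(i) {
    extract_layer_candidates(layers[[i]], pre$enhanced, pre$fov, config,
                             layer_index = i)
  })
  merge_candidates(do.call(rbind, per_layer), config)
}
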