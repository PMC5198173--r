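# Fixture builders and independent brute-force oracles.
# Oracles are deliberately written with plain R loops and their own labeling /
# feature code, sharing only the documented definitions (perimeter = exposed
# 4-neighbour edges, circularity = 4*pi*area/perimeter^2, symmetric mirror
# padding) with the implementation under test.

# --- fixture builders -------------------------------------------------------

# RGB frame of constant gray with a bright disc (the illuminated field).
disc_image <- function(H, W, center, radius, fg = 0.5, bg = 0) {
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  m <- matrix(bg, H, W)
  m[(rows - center[1])^2 + (cols - center[2])^2 <= radius^2] <- fg
  fundus_image(m)
}

# Stamp a hard disc of constant `value` into a matrix (0-based center).
stamp_disc <- function(m, center, diameter, value) {
  H <- nrow(m); W <- ncol(m)
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  sel <- (rows - center[1])^2 + (cols - center[2])^2 <= (diameter / 2)^2
  m[sel] <- value
  m
}

# Stamp an axis-aligned bar (rows x cols extents, 0-based inclusive).
stamp_bar <- function(m, row_range, col_range, value) {
  m[(row_range[1]:row_range[2]) + 1, (col_range[1]:col_range[2]) + 1] <- value
  m
}

# Isotropic Gaussian dip on a constant field, as an intensity image.
dip_image <- function(H, W, center, depth, sigma, level = 0.8) {
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d2 <- (rows - center[1])^2 + (cols - center[2])^2
  level - depth * exp(-d2 / (2 * sigma^2))
}

# Candidates from a raw enhanced map via the package's exported stages.
candidates_from_enhanced <- function(enhanced, fov = NULL,
                                     config = ma_config()) {
  layers <- layer_decompose(enhanced, fov, config)
  per <- lapply(seq_along(layers), function(i) {
    extract_layer_candidates(layers[[i]], enhanced, fov, config,
                             layer_index = i)
  })
  merge_candidates(do.call(rbind, per), config)
}

# --- independent oracles ----------------------------------------------------

mirror1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# Direct 2-D Gaussian convolution with the same kernel definition
# (truncation at ceil(4*sigma), normalized) and symmetric padding.
conv_gauss_oracle <- function(x, sigma) {
  R <- max(1, ceiling(4 * sigma))
  k1 <- exp(-(-R:R)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    acc <- 0
    for (dr in -R:R) for (dc in -R:R) {
      acc <- acc + K[dr + R + 1, dc + R + 1] *
        x[mirror1(r + dr, H), mirror1(c + dc, W)]
    }
    out[r, c] <- acc
  }
  out
}

# Queue-based 8-connected flood-fill labeling.
label8_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (c0 in 1:W) for (r0 in 1:H) {
    if (!m[r0, c0] || lab[r0, c0] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            m[rr, cc] && lab[rr, cc] == 0) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Exhaustive threshold-and-label candidate oracle mirroring the documented
# filter definitions, all in plain loops.
candidate_oracle <- function(enhanced, fov = NULL, config = ma_config()) {
  H <- nrow(enhanced); W <- ncol(enhanced)
  inside <- if (is.null(fov)) enhanced else enhanced[fov$mask]
  top <- quantile(inside, 0.999, names = FALSE)
  tau <- config$depth_threshold
  thresholds <- seq(tau, max(top, tau), length.out = config$n_layers)
  rows <- NULL
  for (t in seq_along(thresholds)) {
    m <- enhanced >= thresholds[t]
    if (!is.null(fov)) m <- m & fov$mask
    if (!any(m)) next
    lab <- label8_oracle(m)
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l, arr.ind = TRUE)
      area <- nrow(idx)
      perim <- 0
      for (i in seq_len(area)) {
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- idx[i, 1] + d[1]; cc <- idx[i, 2] + d[2]
          if (rr < 1 || rr > H || cc < 1 || cc > W || lab[rr, cc] != l) {
            perim <- perim + 1
          }
        }
      }
      w <- enhanced[idx]
      depth <- mean(w)
      if (sum(w) > 0) {
        wr <- sum(w * (idx[, 1] - 1)) / sum(w)
        wc <- sum(w * (idx[, 2] - 1)) / sum(w)
      } else {
        wr <- mean(idx[, 1] - 1); wc <- mean(idx[, 2] - 1)
      }
      eq_diam <- 2 * sqrt(area / pi)
      circ <- 4 * pi * area / perim^2
      margin <- config$border_margin
      ok_border <- wr >= margin && wr <= H - 1 - margin &&
        wc >= margin && wc <= W - 1 - margin
      if (!is.null(fov)) {
        ok_border <- ok_border &&
          sqrt((wr - fov$center[1])^2 + (wc - fov$center[2])^2) <=
            fov$radius - margin
      }
      if (eq_diam >= config$diameter_range[1] &&
          eq_diam <= config$diameter_range[2] &&
          circ >= config$min_circularity &&
          depth >= config$depth_threshold && ok_border) {
        rows <- rbind(rows, data.frame(
          row = wr, col = wc, equivalent_diameter = eq_diam,
          circularity = circ, depth = depth, layer_index = t))
      }
    }
  }
  if (is.null(rows)) {
    return(data.frame(row = numeric(0), col = numeric(0),
                      equivalent_diameter = numeric(0),
                      circularity = numeric(0), depth = numeric(0),
                      layer_index = integer(0)))
  }
  # independent greedy merge: deepest layer, then depth, then centroid
  ord <- order(-rows$layer_index, -rows$depth, rows$row, rows$col)
  rows <- rows[ord, , drop = FALSE]
  kept <- rows[0, ]
  for (i in seq_len(nrow(rows))) {
    if (nrow(kept) == 0) { kept <- rows[i, , drop = FALSE]; next }
    d <- sqrt((kept$row - rows$row[i])^2 + (kept$col - rows$col[i])^2)
    if (all(d > config$merge_radius)) kept <- rbind(kept, rows[i, ])
  }
  rownames(kept) <- NULL
  kept
}

# Canonical ordering for comparing candidate tables.
sort_candidates <- function(df) {
  df <- df[order(df$row, df$col), , drop = FALSE]
  rownames(df) <- NULL
  df
}
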