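#' Extract cross-sectional intensity profiles around a point
#'
#' Samples the intensity along diameter lines through `center` at
#' `n_orient` equally spaced orientations over `[0, 180)` degrees (angle 0 is
#' horizontal, along columns). Each profile has `diameter` samples at 1-px
#' spacing, bilinear-interpolated.
#'
#' @param intensity `H x W` matrix.
#' @param center 0-based `c(row, col)` of the scanning-region centre.
#' @param diameter Scanning-region diameter in px (odd). Default 31.
#' @param n_orient Number of orientations. Default 12.
#' @return A list of class `"profile_set"` with `center`, `diameter`,
#'   `orientations` (degrees) and `raw` (`n_orient x diameter` matrix);
#'   `reconstructed` is `NULL` until [ssa_reconstruct()] is applied.
#' @export
extract_profiles <- function(intensity, center, diameter = 31, n_orient = 12) {
  stopifnot(is.matrix(intensity), length(center) == 2,
            diameter %% 2 == 1, n_orient >= 2)
  H <- nrow(intensity); W <- ncol(intensity)
  half <- (diameter - 1) / 2
  if (center[1] - half < 0 || center[1] + half > H - 1 ||
      center[2] - half < 0 || center[2] + half > W - 1) {
    stop("scanning region crosses the image boundary")
  }
  angles <- (seq_len(n_orient) - 1) * 180 / n_orient
  t_off <- seq(-half, half)
  raw <- matrix(0, n_orient, diameter)
  for (i in seq_len(n_orient)) {
    th <- angles[i] * pi / 180
    rr <- center[1] + t_off * sin(th)
    cc <- center[2] + t_off * cos(th)
    raw[i, ] <- cpp_bilinear(intensity, rr, cc)
  }
  structure(list(center = center, diameter = diameter, orientations = angles,
                 raw = raw, reconstructed = NULL),
            class = "profile_set")
}

#' Singular spectrum analysis reconstruction of a 1-D profile
#'
#' Embeds the profile into its Hankel (trajectory) matrix with window length
#' `window`, takes the singular value decomposition, and reconstructs from
#' the leading `n_components` elementary matrices by diagonal averaging.
#' With `n_components = window` this is the identity; with a small number of
#' components it is a structure-preserving smoother.
#'
#' @param profile Numeric vector of length `L`.
#' @param window Embedding window `w`, `2 <= w <= L - 1`.
#' @param n_components Number of leading components kept,
#'   `1 <= n_components <= window`.
#' @return Reconstructed numeric vector of length `L`.
#' @export
ssa_reconstruct <- function(profile, window = 8, n_components = 2) {
  L <- length(profile)
  stopifnot(window >= 2, window <= L - 1,
            n_components >= 1, n_components <= window)
  if (any(!is.finite(profile))) stop("profile contains non-finite values")
  K <- L - window + 1
  X <- matrix(0, window, K)
  for (j in seq_len(K)) X[, j] <- profile[j:(j + window - 1)]
  sv <- svd(X)
  k <- min(n_components, sum(sv$d > 0))
  if (k == 0) return(rep(0, L))
  Xk <- sv$u[, seq_len(k), drop = FALSE] %*%
    (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
  # diagonal averaging: entry (i, j) contributes to element i + j - 1
  out <- numeric(L)
  cnt <- numeric(L)
  for (j in seq_len(K)) {
    idx <- j:(j + window - 1)
    out[idx] <- out[idx] + Xk[, j]
    cnt[idx] <- cnt[idx] + 1
  }
  out / cnt
}

#' Score the rotational symmetry of a profile set
#'
#' A microaneurysm is a small round dark lesion, so its cross-sectional
#' profiles look alike at every orientation, while vessels and haemorrhages
#' give orientation-dependent profiles. Similarity is measured by Pearson
#' correlation over all orientation pairs of the SSA-reconstructed profiles;
#' the decision uses the worst (minimum) pair. A constant (zero-variance)
#' profile is assigned pairwise correlation 0 — a flat region is not a
#' lesion. The candidate must also show a central dip: on every orientation
#' the central sample must attain the minimum of the central third of the
#' profile (up to 2% of the profile range, so sub-pixel centring cannot flip
#' the flag).
#'
#' @param ps A `"profile_set"`; profiles are SSA-reconstructed here if not
#'   already present.
#' @param config An [ma_config()]; uses `ssa_window`, `ssa_components`,
#'   `symmetry_threshold`.
#' @return A list of class `"ma_score"` with `min_pair_corr`,
#'   `mean_pair_corr`, `center_dip` and `is_ma`.
#' @export
score_symmetry <- function(ps, config = ma_config()) {
  stopifnot(inherits(ps, "profile_set"))
  rec <- ps$reconstructed
  if (is.null(rec)) {
    rec <- t(apply(ps$raw, 1, ssa_reconstruct,
                   window = config$ssa_window,
                   n_components = config$ssa_components))
    ps$reconstructed <- rec
  }
  n <- nrow(rec)
  sds <- apply(rec, 1, sd)
  cors <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cors <- c(cors,
                if (sds[i] < 1e-10 || sds[j] < 1e-10) 0
                else cor(rec[i, ], rec[j, ]))
    }
  }
  L <- ncol(rec)
  mid <- (L + 1) / 2
  third <- max(1, floor(L / 6))
  central <- (mid - third):(mid + third)
  rng <- apply(rec, 1, function(p) max(p) - min(p))
  dips <- vapply(seq_len(n), function(i) {
    rec[i, mid] <= min(rec[i, central]) + 0.02 * max(rng[i], 1e-12)
  }, logical(1))
  min_pc <- min(cors)
  score <- list(min_pair_corr = min_pc,
                mean_pair_corr = mean(cors),
                center_dip = all(dips),
                is_ma = (min_pc >= config$symmetry_threshold) && all(dips))
  structure(score, class = "ma_score")
}

#' Classify candidate lesions by rotational symmetry
#'
#' Stage three of the pipeline. For each candidate, cross-sectional profiles
#' are sampled from the shade-corrected intensity (`1 - darkness`, so
#' illumination gradients cannot break symmetry), SSA-smoothed and scored.
#' Candidates whose scanning disc does not fit inside the image are kept but
#' classified `is_ma = FALSE` with `border_flag = TRUE`.
#'
#' @param pre A `"preprocessed_fundus"`.
#' @param candidates Candidate data frame from [detect_candidates()].
#' @param config An [ma_config()].
#' @return The candidate data frame with columns `min_pair_corr`,
#'   `mean_pair_corr`, `center_dip`, `border_flag` and `is_ma` appended.
#' @export
classify_candidates <- function(pre, candidates, config = ma_config()) {
  stopifnot(inherits(pre, "preprocessed_fundus"), is.data.frame(candidates))
  n <- nrow(candidates)
  out <- candidates
  out$min_pair_corr <- rep(NA_real_, n)
  out$mean_pair_corr <- rep(NA_real_, n)
  out$center_dip <- rep(FALSE, n)
  out$border_flag <- rep(FALSE, n)
  out$is_ma <- rep(FALSE, n)
  if (n == 0) return(out)
  corrected <- pmax(1 - pre$darkness, 0)
  half <- (config$profile_diameter - 1) / 2
  H <- nrow(corrected); W <- ncol(corrected)
  for (i in seq_len(n)) {
    ctr <- c(out$row[i], out$col[i])
    if (ctr[1] - half < 0 || ctr[1] + half > H - 1 ||
        ctr[2] - half < 0 || ctr[2] + half > W - 1) {
      out$border_flag[i] <- TRUE
      next
    }
    ps <- extract_profiles(corrected, ctr,
                           diameter = config$profile_diameter,
                           n_orient = config$n_orientations)
    sc <- score_symmetry(ps, config)
    out$min_pair_corr[i] <- sc$min_pair_corr
    out$mean_pair_corr[i] <- sc$mean_pair_corr
    out$center_dip[i] <- sc$center_dip
    out$is_ma[i] <- sc$is_ma
  }
  out
}
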