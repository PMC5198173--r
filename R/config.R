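#' Pipeline configuration
#'
#' Builds the full configuration for the detection pipeline. All distances are
#' in pixels at the canonical scale, at which the retinal field of view spans
#' `canonical_diameter` pixels and a typical microaneurysm is about seven
#' pixels across.
#'
#' @param canonical_diameter Field-of-view diameter, in px, that every image
#'   is rescaled to before lesion analysis. Default 768.
#' @param crop_margin Margin, in px, kept around the field-of-view bounding
#'   box when cropping. Default 16.
#' @param fov_threshold Intensity (mean of RGB) above which a pixel counts as
#'   inside the illuminated field rather than the dark surround. Default 0.1.
#' @param min_fov_radius Smallest acceptable field-of-view radius, in native
#'   px, for standardization. Default 32.
#' @param quality_min_contrast Minimum vessel-contrast statistic (100 x 95th
#'   percentile of the gradient magnitude of the smoothed green channel
#'   inside the field) for an image to be gradable. Default 0.35, calibrated
#'   on synthetic fixtures: scenes with resolvable vessels score above 0.6,
#'   vessel-free or heavily attenuated scenes below 0.2.
#' @param fov_fraction_bounds Acceptable range for the fraction of the frame
#'   covered by the field of view. Default `c(0.2, 0.95)`.
#' @param center_tolerance Maximum offset of the field-of-view centre from
#'   the frame centre, as a fraction of the frame diagonal. Default 0.15.
#' @param background_window Side, in px, of the square median-filter window
#'   used for the shade-correction background estimate. Default 65 (odd).
#' @param enhance_sigma Standard deviation, in px, of the Gaussian used to
#'   enhance small dark structures. Default 1.
#' @param n_layers Number of nested threshold layers in the dark-object
#'   filter. Default 6.
#' @param depth_threshold Minimum enhanced darkness (`tau_d`) for candidate
#'   pixels; also the lowest layer threshold. Default 0.02.
#' @param diameter_range Admissible equivalent-diameter range for a
#'   candidate, in px. Default `c(3, 11)`, centred on the nominal 7 px
#'   microaneurysm.
#' @param min_circularity Minimum circularity `4*pi*area/perimeter^2` of a
#'   candidate component. Default 0.55; rejects elongated vessel segments.
#' @param merge_radius Candidates closer than this, in px, across layers are
#'   merged. Default 3.
#' @param border_margin Candidates closer than this, in px, to the
#'   field-of-view edge are discarded so the scanning disc fits. Default 16.
#' @param profile_diameter Diameter, in px, of the cross-section scanning
#'   region. Default 31.
#' @param n_orientations Number of equally spaced profile orientations over
#'   `[0, 180)` degrees. Default 12.
#' @param ssa_window SSA embedding window length. Default 8.
#' @param ssa_components Number of leading SSA components kept in the
#'   reconstruction. Default 2.
#' @param symmetry_threshold Minimum pairwise-minimum Pearson correlation
#'   (`theta_sym`) between reconstructed profiles for a candidate to be
#'   confirmed. Default 0.7, calibrated on synthetic fixtures.
#' @return A named list of class `"ma_config"`.
#' @export
ma_config <- function(canonical_diameter = 768,
                      crop_margin = 16,
                      fov_threshold = 0.1,
                      min_fov_radius = 32,
                      quality_min_contrast = 0.35,
                      fov_fraction_bounds = c(0.2, 0.95),
                      center_tolerance = 0.15,
                      background_window = 65,
                      enhance_sigma = 1,
                      n_layers = 6,
                      depth_threshold = 0.02,
                      diameter_range = c(3, 11),
                      min_circularity = 0.55,
                      merge_radius = 3,
                      border_margin = 16,
                      profile_diameter = 31,
                      n_orientations = 12,
                      ssa_window = 8,
                      ssa_components = 2,
                      symmetry_threshold = 0.7) {
  cfg <- list(
    canonical_diameter = canonical_diameter,
    crop_margin = crop_margin,
    fov_threshold = fov_threshold,
    min_fov_radius = min_fov_radius,
    quality_min_contrast = quality_min_contrast,
    fov_fraction_bounds = fov_fraction_bounds,
    center_tolerance = center_tolerance,
    background_window = background_window,
    enhance_sigma = enhance_sigma,
    n_layers = n_layers,
    depth_threshold = depth_threshold,
    diameter_range = diameter_range,
    min_circularity = min_circularity,
    merge_radius = merge_radius,
    border_margin = border_margin,
    profile_diameter = profile_diameter,
    n_orientations = n_orientations,
    ssa_window = ssa_window,
    ssa_components = ssa_components,
    symmetry_threshold = symmetry_threshold
  )
  stopifnot(
    canonical_diameter >= 64,
    background_window %% 2 == 1, background_window >= 3,
    n_layers >= 2,
    depth_threshold > 0,
    length(diameter_range) == 2, diff(diameter_range) >= 0,
    min_circularity > 0, min_circularity <= 1,
    profile_diameter %% 2 == 1, profile_diameter >= 5,
    n_orientations >= 2,
    ssa_window >= 2, ssa_window <= profile_diameter - 1,
    ssa_components >= 1, ssa_components <= ssa_window,
    symmetry_threshold >= -1, symmetry_threshold <= 1
  )
  structure(cfg, class = "ma_config")
}

#' Load a configuration from a YAML or JSON file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [ma_config()] list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- names(formals(ma_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(ma_config, vals)
}
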