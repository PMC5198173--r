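#' Detect microaneurysms in one image
#'
#' Full three-stage pipeline on a single photograph: preprocessing (with
#' quality gate), candidate extraction, symmetry classification, and the
#' image-level screening decision.
#'
#' @param img A [fundus_image()].
#' @param config An [ma_config()].
#' @return A list with `decision` (one-row data frame from [decide()]),
#'   `candidates` (classified candidate data frame, `NULL` on rejection),
#'   `scale_factor`, and `rejection` (a `"fundus_rejection"` or `NULL`).
#' @export
detect_image <- function(img, config = ma_config()) {
  pre <- preprocess_image(img, config)
  if (inherits(pre, "fundus_rejection")) {
    return(list(decision = decide(pre), candidates = NULL,
                scale_factor = NA_real_, rejection = pre))
  }
  cand <- detect_candidates(pre, config)
  cls <- classify_candidates(pre, cand, config)
  list(decision = decide(cls, image_id = img$image_id),
       candidates = cls, scale_factor = pre$scale_factor,
       crop_offset = pre$crop_offset, rejection = NULL)
}

#' Run detection over a directory or list of images
#'
#' Processes every readable PNG/TIFF/JPEG image, writes one JSON detection
#' file per image plus a summary CSV and a JSON run manifest, and returns
#' the manifest. Centroids are reported 0-based, in canonical and native
#' coordinates (via the recorded scale factor); unreadable files are logged
#' and recorded as skipped.
#'
#' @param input Directory containing images, or character vector of paths.
#' @param out_dir Output directory (created if needed).
#' @param config An [ma_config()].
#' @return The manifest as a list (invisibly written to
#'   `manifest.json`); `$images` has one record per input image.
#' @export
run_detect <- function(input, out_dir, config = ma_config()) {
  paths <- if (length(input) == 1 && dir.exists(input)) {
    list.files(input, pattern = "\\.(png|tiff?|jpe?g)$", ignore.case = TRUE,
               full.names = TRUE)
  } else {
    input
  }
  if (length(paths) == 0) stop("no input images found")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- list()
  rows <- list()
  n_failed <- 0
  for (path in sort(paths)) {
    id <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      img <- read_fundus(path)
      detect_image(img, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", path, ": ", conditionMessage(res))
      n_failed <- n_failed + 1
      records[[id]] <- list(image_id = id, status = "skipped",
                            reason = conditionMessage(res))
      next
    }
    if (!is.null(res$rejection)) {
      records[[id]] <- list(image_id = id, status = "ungradable",
                            reasons = res$rejection$report$reasons)
      rows[[id]] <- data.frame(image_id = id, gradable = FALSE,
                               n_candidates = NA_integer_,
                               n_mas = NA_integer_, dr_positive = NA)
      next
    }
    cls <- res$candidates
    mas <- cls[cls$is_ma, , drop = FALSE]
    det <- list(
      image_id = id,
      coordinate_convention = "0-based (row, col)",
      scale_factor = res$scale_factor,
      detections = if (nrow(mas) == 0) list() else lapply(seq_len(nrow(mas)),
        function(i) list(
          row_canonical = mas$row[i], col_canonical = mas$col[i],
          row_native = mas$row[i] / res$scale_factor + res$crop_offset[1],
          col_native = mas$col[i] / res$scale_factor + res$crop_offset[2],
          equivalent_diameter = mas$equivalent_diameter[i],
          min_pair_corr = mas$min_pair_corr[i]))
    )
    jsonlite::write_json(det, file.path(out_dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    records[[id]] <- list(image_id = id, status = "ok",
                          n_candidates = nrow(cls), n_mas = nrow(mas),
                          dr_positive = nrow(mas) >= 1)
    rows[[id]] <- data.frame(image_id = id, gradable = TRUE,
                             n_candidates = nrow(cls), n_mas = nrow(mas),
                             dr_positive = nrow(mas) >= 1)
  }
  if (n_failed == length(paths)) stop("all input images failed to process")

  summary_df <- do.call(rbind, rows[order(names(rows))])
  write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
  manifest <- list(
    tool = "fundusMA",
    version = as.character(utils::packageVersion("fundusMA")),
    config = unclass(config),
    coordinate_convention = "0-based (row, col)",
    images = unname(records)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate cohorts to disk
#'
#' Renders each cohort of `specs` and writes PNG images plus a single
#' `truth.csv` (one row per image: `image_id`, `cohort`, `has_ma`; one row
#' per lesion: `type`, `row`, `col`, `diameter`, `depth`, 0-based
#' coordinates).
#'
#' @param specs A [cohort_spec()] or list of them (e.g.
#'   [six_cohort_preset()]).
#' @param out_dir Output directory.
#' @param ... [scene_params()] overrides.
#' @return Path to `truth.csv`, invisibly.
#' @export
run_simulate <- function(specs, out_dir, ...) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth_rows <- list()
  for (spec in specs) {
    plan <- cohort_plan(spec)
    for (i in seq_len(nrow(plan))) {
      sc <- generate_scene(plan_scene_params(plan[i, ], ...))
      id <- plan$image_id[i]
      sc$image$image_id <- id
      write_fundus_png(sc$image, file.path(out_dir, paste0(id, ".png")))
      les <- sc$truth$lesions
      truth_rows[[id]] <- if (nrow(les) == 0) {
        data.frame(image_id = id, cohort = plan$cohort[i],
                   has_ma = sc$truth$has_ma, type = NA_character_,
                   row = NA_real_, col = NA_real_,
                   diameter = NA_real_, depth = NA_real_)
      } else {
        data.frame(image_id = id, cohort = plan$cohort[i],
                   has_ma = sc$truth$has_ma, les)
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  path <- file.path(out_dir, "truth.csv")
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Evaluate detection decisions against ground truth
#'
#' Joins per-image decisions to truth on `image_id`, computes per-cohort
#' confusion counts and the screening summary. Unmatched image ids are
#' reported with a warning and excluded; ungradable images are excluded from
#' the confusion counts.
#'
#' @param decisions Data frame with `image_id`, `gradable`, `dr_positive`
#'   (e.g. the summary CSV written by [run_detect()], plus a `cohort`
#'   column, or decisions assembled with [decide()]).
#' @param truth Data frame with `image_id`, `cohort` and `has_ma` (lesion
#'   rows as written by [run_simulate()] are collapsed per image).
#' @param prevalence_table Named prevalences for standardization.
#' @return A `"screening_summary"`.
#' @export
run_evaluate <- function(decisions, truth,
                         prevalence_table = default_prevalence_table()) {
  truth_img <- unique(truth[, c("image_id", "cohort", "has_ma")])
  merged <- merge(decisions, truth_img, by = "image_id")
  missing <- setdiff(decisions$image_id, truth_img$image_id)
  if (length(missing) > 0) {
    warning(length(missing), " image id(s) missing from truth; excluded: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  merged <- merged[merged$gradable, , drop = FALSE]
  merged$truth_positive <- merged$has_ma
  stats <- lapply(split(merged, merged$cohort), function(d) {
    confusion(d, cohort = d$cohort[1])
  })
  summarize_screening(unname(stats), prevalence_table)
}
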