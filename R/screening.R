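#' Image-level screening decision
#'
#' An image is DR-positive when at least one confirmed microaneurysm is
#' present; images where none are detected are considered free of DR.
#' Ungradable images carry no decision.
#'
#' @param classified Classified candidate data frame from
#'   [classify_candidates()], or a `"fundus_rejection"`.
#' @param image_id Identifier recorded in the decision.
#' @param truth_positive Optional ground-truth label.
#' @return A one-row data frame with `image_id`, `gradable`, `n_mas`,
#'   `dr_positive`, `truth_positive` (`NA` when unknown).
#' @export
decide <- function(classified, image_id = "img", truth_positive = NA) {
  if (inherits(classified, "fundus_rejection")) {
    return(data.frame(image_id = classified$image_id, gradable = FALSE,
                      n_mas = NA_integer_, dr_positive = NA,
                      truth_positive = truth_positive))
  }
  n_mas <- sum(classified$is_ma)
  data.frame(image_id = image_id, gradable = TRUE,
             n_mas = as.integer(n_mas), dr_positive = n_mas >= 1,
             truth_positive = truth_positive)
}

#' Confusion counts and sensitivity/specificity for one cohort
#'
#' Takes ground truth as the gold standard. Sensitivity is the proportion of
#' truth-positive images the system flags; specificity the proportion of
#' truth-negative images it clears. Ungradable images must be excluded
#' before calling.
#'
#' @param decisions Data frame of gradable decisions with `dr_positive` and
#'   `truth_positive` (no `NA`).
#' @param cohort Cohort label.
#' @return A list of class `"cohort_stats"` with `cohort`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`.
#' @export
confusion <- function(decisions, cohort = "cohort") {
  stopifnot(is.data.frame(decisions),
            !anyNA(decisions$dr_positive), !anyNA(decisions$truth_positive))
  tp <- sum(decisions$dr_positive & decisions$truth_positive)
  fp <- sum(decisions$dr_positive & !decisions$truth_positive)
  tn <- sum(!decisions$dr_positive & !decisions$truth_positive)
  fn <- sum(!decisions$dr_positive & decisions$truth_positive)
  if (tp + fn == 0) stop("sensitivity undefined: no truth-positive images")
  if (tn + fp == 0) stop("specificity undefined: no truth-negative images")
  structure(list(cohort = cohort, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp)),
            class = "cohort_stats")
}

#' Population standard deviation of percentage values
#'
#' Dispersion of per-cohort percentages (e.g. sensitivities across
#' countries), in percentage points. Uses the population form (divisor `n`):
#' the cohorts studied are the whole population of interest, not a sample
#' from a larger one.
#'
#' @param values Numeric vector of percentages (at least 2).
#' @return Population standard deviation, in percentage points.
#' @export
population_sd <- function(values) {
  if (length(values) < 2) stop("population_sd needs at least 2 values")
  m <- mean(values)
  sqrt(mean((values - m)^2))
}

#' Prevalence-standardized positive predictive value
#'
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))`: the
#' predictive value the test would have in a population with the given
#' disease prevalence, independent of the study sample's case mix.
#'
#' @param sens Sensitivity as a fraction.
#' @param spec Specificity as a fraction.
#' @param prev Assumed population prevalence as a fraction.
#' @return PPV as a fraction.
#' @export
standardized_ppv <- function(sens, spec, prev) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1, prev >= 0, prev <= 1)
  den <- sens * prev + (1 - spec) * (1 - prev)
  if (any(den == 0)) stop("PPV undefined: no positive test results")
  sens * prev / den
}

#' Prevalence-standardized negative predictive value
#'
#' `NPV = spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)`.
#'
#' @inheritParams standardized_ppv
#' @return NPV as a fraction.
#' @export
standardized_npv <- function(sens, spec, prev) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1, prev >= 0, prev <= 1)
  den <- spec * (1 - prev) + (1 - sens) * prev
  if (any(den == 0)) stop("NPV undefined: no negative test results")
  spec * (1 - prev) / den
}

#' Default assumed DR prevalences for predictive-value standardization
#'
#' Known prevalence of DR among patients with diabetes in the racial group of
#' each cohort: 27% for China and Mongolia, 56% for Kenya and Botswana, 47%
#' for Norway and the UK.
#'
#' @return Named numeric vector of fractions.
#' @export
default_prevalence_table <- function() {
  c(Kenya = 0.56, Botswana = 0.56, Norway = 0.47, UK = 0.47,
    China = 0.27, Mongolia = 0.27)
}

#' Summarize screening performance across cohorts
#'
#' Attaches the cross-cohort population standard deviations of sensitivity
#' and specificity (percentage points) and per-cohort standardized PPV/NPV
#' at the assumed prevalences.
#'
#' @param stats_list List of `"cohort_stats"` from [confusion()].
#' @param prevalence_table Named vector of assumed prevalences (fractions)
#'   keyed by cohort name. Default [default_prevalence_table()].
#' @return A list of class `"screening_summary"` with `per_cohort` (data
#'   frame: cohort, tp, fp, tn, fn, sensitivity, specificity,
#'   assumed_prevalence, ppv, npv), `sd_sensitivity` and `sd_specificity`
#'   (percentage points; `NA` with fewer than two cohorts).
#' @export
summarize_screening <- function(stats_list,
                                prevalence_table = default_prevalence_table()) {
  stopifnot(length(stats_list) >= 1,
            all(vapply(stats_list, inherits, logical(1), "cohort_stats")))
  per <- do.call(rbind, lapply(stats_list, function(s) {
    if (!s$cohort %in% names(prevalence_table)) {
      stop("cohort '", s$cohort, "' missing from the prevalence table")
    }
    prev <- prevalence_table[[s$cohort]]
    data.frame(cohort = s$cohort, tp = s$tp, fp = s$fp, tn = s$tn, fn = s$fn,
               sensitivity = s$sensitivity, specificity = s$specificity,
               assumed_prevalence = prev,
               ppv = standardized_ppv(s$sensitivity, s$specificity, prev),
               npv = standardized_npv(s$sensitivity, s$specificity, prev))
  }))
  sd_sens <- sd_spec <- NA_real_
  if (nrow(per) >= 2) {
    sd_sens <- population_sd(100 * per$sensitivity)
    sd_spec <- population_sd(100 * per$specificity)
  }
  structure(list(per_cohort = per, sd_sensitivity = sd_sens,
                 sd_specificity = sd_spec),
            class = "screening_summary")
}

#' @export
print.screening_summary <- function(x, ...) {
  p <- x$per_cohort
  cat("Screening summary\n")
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-10s sens %5.1f%%  spec %5.1f%%  PPV %3.0f%%  NPV %3.0f%% (prev %2.0f%%)\n",
                p$cohort[i], 100 * p$sensitivity[i], 100 * p$specificity[i],
                100 * p$ppv[i], 100 * p$npv[i],
                100 * p$assumed_prevalence[i]))
  }
  if (!is.na(x$sd_sensitivity)) {
    cat(sprintf("  SD across cohorts: sensitivity %.1f pp, specificity %.1f pp\n",
                x$sd_sensitivity, x$sd_specificity))
  }
  invisible(x)
}
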