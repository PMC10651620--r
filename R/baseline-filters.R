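# Baseline eligibility filtering. "Baseline" is a subject's first visit with
# all three of metabolomics, memory and gait measured concurrently; visits
# before baseline are dropped from the analytic copy.

#' Find each subject's baseline visit
#'
#' Baseline is the first (earliest `time_years`) visit at which metabolomics,
#' memory and gait speed are all present.
#'
#' @param dataset A `cohort_dataset`.
#' @return Data frame with one row per subject that has a baseline:
#'   `subject_id`, `visit_id`, `baseline_time`, `age_at_baseline`,
#'   `baseline_gait`, `baseline_memory`, `baseline_calendar_year`.
#' @export
find_baseline <- function(dataset) {
  v <- dataset$visits
  has_met <- v$visit_id %in% rownames(dataset$panel$conc)
  ok <- has_met & !is.na(v$memory_score) & !is.na(v$gait_speed_mps)
  v <- v[ok, , drop = FALSE]
  v <- v[order(v$subject_id, v$time_years), , drop = FALSE]
  first <- v[!duplicated(v$subject_id), , drop = FALSE]
  age0 <- dataset$subjects$baseline_age_years[
    match(first$subject_id, dataset$subjects$subject_id)]
  data.frame(
    subject_id = first$subject_id,
    visit_id = first$visit_id,
    baseline_time = first$time_years,
    age_at_baseline = age0 + first$time_years,
    baseline_gait = first$gait_speed_mps,
    baseline_memory = first$memory_score,
    baseline_calendar_year = first$calendar_year,
    stringsAsFactors = FALSE)
}

#' Apply baseline eligibility filters
#'
#' Removes subjects whose baseline visit (first concurrent metabolomics /
#' memory / gait assessment) violates any inclusion criterion: minimum age at
#' baseline, minimum usual gait speed, or (optionally) complete baseline
#' covariates (sex, race, education, APOE e4, age). Visits before a kept
#' subject's baseline are dropped. Filtering is idempotent.
#'
#' @param dataset A `cohort_dataset`.
#' @param min_age Minimum age at baseline in years (default 50).
#' @param min_gait Minimum baseline gait speed in m/s (default 0.6).
#' @param require_covariates Exclude subjects with any missing baseline
#'   covariate (default `TRUE`); no covariate imputation is performed.
#' @return List with `dataset` (the filtered copy) and `exclusions`, a data
#'   frame of one row per removed subject with a `;`-joined `reason` string
#'   (`"no_baseline"`, `"age<50"`, `"gait<0.6"`, `"missing_covariates"`).
#' @export
apply_baseline_filters <- function(dataset, min_age = 50, min_gait = 0.6,
                                   require_covariates = TRUE) {
  validate_cohort_dataset(dataset)
  base <- find_baseline(dataset)
  subj <- dataset$subjects

  reasons <- setNames(vector("list", nrow(subj)), subj$subject_id)
  bi <- match(subj$subject_id, base$subject_id)
  for (k in seq_len(nrow(subj))) {
    id <- subj$subject_id[k]
    r <- character(0)
    if (is.na(bi[k])) {
      r <- "no_baseline"
    } else {
      b <- base[bi[k], ]
      if (b$age_at_baseline < min_age)
        r <- c(r, sprintf("age<%g", min_age))
      if (b$baseline_gait < min_gait)
        r <- c(r, sprintf("gait<%g", min_gait))
      if (require_covariates) {
        cov_na <- is.na(subj$sex[k]) || is.na(subj$race[k]) ||
          is.na(subj$education_years[k]) || is.na(subj$apoe4_carrier[k]) ||
          is.na(subj$baseline_age_years[k])
        if (cov_na) r <- c(r, "missing_covariates")
      }
    }
    reasons[[id]] <- r
  }
  excluded <- names(reasons)[lengths(reasons) > 0]
  exclusions <- data.frame(
    subject_id = excluded,
    reason = vapply(reasons[excluded], paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  keep <- setdiff(subj$subject_id, excluded)
  if (!length(keep)) stop("no eligible subjects after baseline filtering",
                          call. = FALSE)

  subjects <- subj[subj$subject_id %in% keep, , drop = FALSE]
  visits <- dataset$visits[dataset$visits$subject_id %in% keep, , drop = FALSE]
  bt <- base$baseline_time[match(visits$subject_id, base$subject_id)]
  visits <- visits[visits$time_years >= bt, , drop = FALSE]
  rownames(subjects) <- rownames(visits) <- NULL

  pk <- rownames(dataset$panel$conc) %in% visits$visit_id
  panel <- dataset$panel
  panel$conc <- panel$conc[pk, , drop = FALSE]
  panel$below_lod <- panel$below_lod[pk, , drop = FALSE]

  out <- new_cohort_dataset(subjects, visits, panel,
                            provenance = c(dataset$provenance,
                                           list(baseline_filtered = TRUE)))
  list(dataset = out, exclusions = exclusions)
}
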