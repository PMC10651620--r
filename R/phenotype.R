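# Trajectory-based phenotype classification: per-subject annual rates of
# change in memory and gait speed by simple linear regression, tertile
# cut-points on the signed slopes, and the four-group classification.
#
# Sign convention: everything operates on signed slopes. A published
# "decline of 0.67 points/year" is the signed cut-point -0.67; a subject is
# memory-declining iff memory_slope <= memory_cut (ties fall in the declining
# tertile, since the lowest tertile includes its boundary).

ols_slope <- function(t, y) {
  tc <- t - mean(t)
  s2 <- sum(tc^2)
  if (s2 == 0) return(NA_real_)
  sum(tc * (y - mean(y))) / s2
}

#' Estimate per-subject annual rates of change
#'
#' For each subject, fits a simple linear regression of memory score on time
#' and of gait speed on time, over the subject's eligible visits. Visits at or
#' after the subject's dementia onset are excluded when
#' `exclude_post_dementia` is `TRUE`, because the phenotype is defined by
#' pre-diagnosis decline. Subjects with fewer than `min_visits` eligible
#' points for either outcome (or no variation in visit times) are omitted and
#' logged.
#'
#' @param dataset A `cohort_dataset`.
#' @param min_visits Minimum eligible visits per outcome (default 2, the
#'   minimum that defines a slope).
#' @param exclude_post_dementia Drop visits with `time_years >=
#'   dementia_onset_time` (default `TRUE`).
#' @return Data frame `subject_id`, `memory_slope` (points/yr), `gait_slope`
#'   (m/s/yr), `n_points_memory`, `n_points_gait`, with an `"omitted"`
#'   attribute logging excluded subjects and reasons.
#' @export
estimate_annual_slopes <- function(dataset, min_visits = 2,
                                   exclude_post_dementia = TRUE) {
  stopifnot(min_visits >= 2)
  v <- dataset$visits
  onset <- dataset$subjects$dementia_onset_time[
    match(v$subject_id, dataset$subjects$subject_id)]
  if (exclude_post_dementia)
    v <- v[is.na(onset) | v$time_years < onset, , drop = FALSE]

  ids <- unique(dataset$subjects$subject_id)
  rows <- vector("list", length(ids))
  omitted <- list()
  for (k in seq_along(ids)) {
    vi <- v[v$subject_id == ids[k], , drop = FALSE]
    mem <- !is.na(vi$memory_score)
    gat <- !is.na(vi$gait_speed_mps)
    if (sum(mem) < min_visits || sum(gat) < min_visits) {
      omitted[[ids[k]]] <- "fewer than min_visits eligible points"
      next
    }
    ms <- ols_slope(vi$time_years[mem], vi$memory_score[mem])
    gs <- ols_slope(vi$time_years[gat], vi$gait_speed_mps[gat])
    if (is.na(ms) || is.na(gs)) {
      omitted[[ids[k]]] <- "no variation in visit times"
      next
    }
    rows[[k]] <- data.frame(subject_id = ids[k], memory_slope = ms,
                            gait_slope = gs, n_points_memory = sum(mem),
                            n_points_gait = sum(gat),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(subject_id = character(0), memory_slope = numeric(0),
                      gait_slope = numeric(0), n_points_memory = integer(0),
                      n_points_gait = integer(0))
  rownames(out) <- NULL
  attr(out, "omitted") <- data.frame(
    subject_id = names(omitted),
    reason = unlist(omitted, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE)
  out
}

#' Lowest-tertile cut-points of annual change
#'
#' Returns the 33 1/3 empirical percentile of the signed memory and gait
#' slopes, using linear interpolation between order statistics (the R default
#' quantile definition, type 7). Externally published cut-points can be used
#' instead via the `override` argument of [classify_phenotypes()] callers.
#'
#' @param slopes Data frame from [estimate_annual_slopes()].
#' @return List of class `cutpoints` with `memory_cut` (points/yr) and
#'   `gait_cut` (m/s/yr), both signed.
#' @export
tertile_cutpoints <- function(slopes) {
  if (nrow(slopes) < 3)
    stop("at least 3 subjects are required to form tertiles", call. = FALSE)
  structure(list(
    memory_cut = unname(quantile(slopes$memory_slope, 1 / 3, type = 7)),
    gait_cut = unname(quantile(slopes$gait_slope, 1 / 3, type = 7))),
    class = "cutpoints")
}

#' Classify subjects into the four phenotype groups
#'
#' A subject is memory-declining iff `memory_slope <= memory_cut` and
#' gait-declining iff `gait_slope <= gait_cut`; `dual_decline` is both,
#' `no_decline` neither, and the two single-decline groups are the remaining
#' cases. The four labels partition the classified subjects. Subjects with a
#' missing slope are omitted and logged.
#'
#' @param slopes Data frame from [estimate_annual_slopes()].
#' @param cutpoints A `cutpoints` object (from [tertile_cutpoints()] or built
#'   manually, e.g. `structure(list(memory_cut = -0.67, gait_cut = -0.022),
#'   class = "cutpoints")` to apply published cuts).
#' @return Data frame `subject_id`, `label` (factor with levels
#'   [phenotype_levels()]), with an `"omitted"` attribute.
#' @export
classify_phenotypes <- function(slopes, cutpoints) {
  stopifnot(inherits(cutpoints, "cutpoints"),
            is.finite(cutpoints$memory_cut), is.finite(cutpoints$gait_cut))
  ok <- !is.na(slopes$memory_slope) & !is.na(slopes$gait_slope)
  s <- slopes[ok, , drop = FALSE]
  mem_dec <- s$memory_slope <= cutpoints$memory_cut
  gait_dec <- s$gait_slope <= cutpoints$gait_cut
  label <- ifelse(mem_dec & gait_dec, "dual_decline",
           ifelse(mem_dec, "memory_decline_only",
           ifelse(gait_dec, "gait_decline_only", "no_decline")))
  out <- data.frame(subject_id = s$subject_id,
                    label = factor(label, levels = phenotype_levels()),
                    stringsAsFactors = FALSE)
  attr(out, "omitted") <- data.frame(
    subject_id = slopes$subject_id[!ok],
    reason = rep("missing slope", sum(!ok)), stringsAsFactors = FALSE)
  out
}
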