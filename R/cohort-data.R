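# Core data container: a longitudinal cohort with subjects, visits, and a
# visit-aligned quantified metabolite panel (concentrations in uM plus
# per-metabolite limit of detection).

SUBJECT_COLS <- c("subject_id", "sex", "race", "education_years",
                  "apoe4_carrier", "baseline_age_years", "dementia_onset_time")
VISIT_COLS <- c("visit_id", "subject_id", "time_years", "calendar_year",
                "gait_speed_mps", "memory_score")
PANEL_META_COLS <- c("metabolite", "class", "lod")

#' Phenotype group labels
#'
#' The four trajectory-defined phenotype groups, in reference order
#' (`no_decline` first, so it is the reference level in all models).
#' @return Character vector of the four group labels.
#' @export
phenotype_levels <- function() {
  c("no_decline", "memory_decline_only", "gait_decline_only", "dual_decline")
}

#' Construct a cohort dataset
#'
#' Assembles and validates the single in-memory study object used by all
#' pipeline stages.
#'
#' @param subjects Data frame with columns `subject_id`, `sex`
#'   (`"male"`/`"female"`), `race`, `education_years`, `apoe4_carrier`
#'   (logical), `baseline_age_years` (age at study time 0) and
#'   `dementia_onset_time` (years on the visit time axis; `NA` if never
#'   diagnosed).
#' @param visits Data frame with columns `visit_id`, `subject_id`,
#'   `time_years`, `calendar_year`, `gait_speed_mps` (usual gait over 6 m,
#'   m/s), `memory_score` (CVLT immediate recall total, 0-80). Either outcome
#'   may be `NA` at a given visit.
#' @param panel List with `meta` (data frame `metabolite`, `class`, `lod`) and
#'   `conc`, a visits x metabolites concentration matrix (uM) whose rownames
#'   are `visit_id`s of the visits that have metabolomics. An optional
#'   `below_lod` logical matrix marks censored values; if absent it is derived
#'   as `conc < lod`.
#' @param provenance Free-form list recording where the data came from
#'   (file paths or a simulation seed).
#' @return An object of class `cohort_dataset`.
#' @export
new_cohort_dataset <- function(subjects, visits, panel, provenance = list()) {
  if (is.null(panel$below_lod)) {
    panel$below_lod <- sweep(panel$conc, 2, panel$meta$lod, `<`)
    panel$below_lod[is.na(panel$below_lod)] <- FALSE
  }
  x <- structure(
    list(subjects = as.data.frame(subjects), visits = as.data.frame(visits),
         panel = panel, provenance = provenance),
    class = "cohort_dataset")
  validate_cohort_dataset(x)
  x
}

#' Validate a cohort dataset
#'
#' Checks the schema, uniqueness and referential-integrity invariants and the
#' instrument ranges (memory in 0-80, gait > 0, LOD finite and positive).
#'
#' @param x A `cohort_dataset`.
#' @return `x`, invisibly, if valid; otherwise an error naming the violation.
#' @export
validate_cohort_dataset <- function(x) {
  stopifnot(inherits(x, "cohort_dataset"))
  require_columns(x$subjects, SUBJECT_COLS, "subjects table")
  require_columns(x$visits, VISIT_COLS, "visits table")
  require_columns(x$panel$meta, PANEL_META_COLS, "metabolite metadata table")

  if (anyDuplicated(x$subjects$subject_id))
    stop("duplicate subject_id in subjects table", call. = FALSE)
  if (anyDuplicated(x$visits$visit_id))
    stop("duplicate visit_id in visits table", call. = FALSE)
  if (anyDuplicated(x$visits[, c("subject_id", "time_years")]))
    stop("duplicate (subject_id, time_years) in visits table", call. = FALSE)
  if (!all(is.finite(x$subjects$baseline_age_years)))
    stop("baseline_age_years must be finite", call. = FALSE)

  orphan <- setdiff(x$visits$subject_id, x$subjects$subject_id)
  if (length(orphan))
    stop("referential integrity: visit references unknown subject '",
         orphan[1], "'", call. = FALSE)

  conc <- x$panel$conc
  if (is.null(rownames(conc)))
    stop("panel concentration matrix must have visit_id rownames", call. = FALSE)
  bad_visit <- setdiff(rownames(conc), x$visits$visit_id)
  if (length(bad_visit))
    stop("referential integrity: panel row references unknown visit '",
         bad_visit[1], "'", call. = FALSE)
  if (!identical(colnames(conc), x$panel$meta$metabolite))
    stop("panel columns must match metabolite metadata (name and order)",
         call. = FALSE)

  mem <- x$visits$memory_score
  if (any(!is.na(mem) & (mem < 0 | mem > 80)))
    stop("memory_score outside instrument range [0, 80]", call. = FALSE)
  gait <- x$visits$gait_speed_mps
  if (any(!is.na(gait) & gait <= 0))
    stop("gait_speed_mps must be positive", call. = FALSE)
  lod <- x$panel$meta$lod
  if (any(!is.finite(lod) | lod <= 0))
    stop("per-metabolite lod must be finite and positive", call. = FALSE)
  if (any(!is.na(conc) & conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", nrow(x$subjects), " subjects, ",
      nrow(x$visits), " visits, ",
      nrow(x$panel$conc), " metabolomics visits x ",
      ncol(x$panel$conc), " metabolites\n", sep = "")
  invisible(x)
}

#' Read a cohort from delimited files
#'
#' Reads the four cohort tables (subjects, visits, metabolite concentrations,
#' metabolite metadata) and returns a validated [new_cohort_dataset()] object.
#' The delimiter is chosen by extension: comma for `.csv`, tab otherwise.
#' Below-LOD flags are set wherever a concentration is below the metabolite's
#' LOD.
#'
#' @param subjects_path,visits_path,panel_path,panel_meta_path File paths.
#'   `panel_path` holds one `visit_id` column plus one column per metabolite.
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(subjects_path, visits_path, panel_path,
                        panel_meta_path) {
  subjects <- read_table_auto(subjects_path)
  visits <- read_table_auto(visits_path)
  panel_df <- read_table_auto(panel_path)
  meta <- read_table_auto(panel_meta_path)

  require_columns(subjects, SUBJECT_COLS, "subjects file")
  require_columns(visits, VISIT_COLS, "visits file")
  require_columns(meta, PANEL_META_COLS, "metabolite metadata file")
  require_columns(panel_df, "visit_id", "metabolite panel file")

  subjects$apoe4_carrier <- as.logical(subjects$apoe4_carrier)
  conc <- as.matrix(panel_df[, setdiff(names(panel_df), "visit_id"),
                             drop = FALSE])
  rownames(conc) <- panel_df$visit_id
  miss <- setdiff(colnames(conc), meta$metabolite)
  if (length(miss))
    stop("metabolite '", miss[1], "' in panel file has no metadata row",
         call. = FALSE)
  meta <- meta[match(colnames(conc), meta$metabolite), , drop = FALSE]
  rownames(meta) <- NULL

  new_cohort_dataset(
    subjects, visits, list(meta = meta, conc = conc),
    provenance = list(source = normalizePath(subjects_path, mustWork = FALSE)))
}

#' Write a cohort to delimited files
#'
#' Inverse of [read_cohort()]: emits `subjects.csv`, `visits.csv`,
#' `metabolites.csv` and `metabolite_meta.csv` under `dir`.
#'
#' @param dataset A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  validate_cohort_dataset(dataset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    visits = file.path(dir, "visits.csv"),
    panel = file.path(dir, "metabolites.csv"),
    panel_meta = file.path(dir, "metabolite_meta.csv"))
  write_table_auto(dataset$subjects, paths[["subjects"]])
  write_table_auto(dataset$visits, paths[["visits"]])
  panel_df <- data.frame(visit_id = rownames(dataset$panel$conc),
                         dataset$panel$conc, check.names = FALSE)
  write_table_auto(panel_df, paths[["panel"]])
  write_table_auto(dataset$panel$meta, paths[["panel_meta"]])
  invisible(paths)
}

#' Write result tables and a run manifest
#'
#' Writes each table in `tables` as a TSV with stable column order, plus a
#' `manifest.json` capturing configuration, seed and package version so a run
#' can be reproduced exactly.
#'
#' @param tables Non-empty named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param manifest List merged into the manifest (e.g. config and seed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, manifest = list()) {
  if (!length(tables) || is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a non-empty named list", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_table_auto(as.data.frame(tables[[nm]]), p)
    paths[nm] <- p
  }
  manifest <- c(manifest,
                list(package = "dualtraj",
                     version = as.character(packageVersion("dualtraj")),
                     tables = names(tables)))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths["manifest"] <- mp
  invisible(paths)
}
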