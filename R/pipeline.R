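# Pipeline orchestration: configuration, staged execution with persisted
# tables, a JSON manifest, and a regenerable markdown run report.

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Arguments not
#' supplied keep their defaults; unknown names are rejected (also when
#' loading from file via [load_pipeline_config()]).
#'
#' @param seed Global seed; stage seeds are derived from it deterministically.
#' @param scale Simulation scale (`"smoke"`, `"desk"`, `"full"`) used when no
#'   `inputs` are given.
#' @param inputs Optional named list of file paths (`subjects`, `visits`,
#'   `panel`, `panel_meta`) to analyze real data instead of simulating.
#' @param out_dir Output directory.
#' @param min_age,min_gait,require_covariates Baseline filters (see
#'   [apply_baseline_filters()]).
#' @param min_visits,exclude_post_dementia Slope estimation (see
#'   [estimate_annual_slopes()]).
#' @param override_cuts Optional numeric `c(memory_cut, gait_cut)` (signed
#'   slopes) replacing internally computed tertile cut-points, e.g.
#'   `c(-0.67, -0.022)` to apply externally published cuts.
#' @param max_below_frac,min_fit LOD filtering and imputation.
#' @param alpha Significance threshold for ratio and module contrasts.
#' @param m_total Optional explicit BH family size for the metabolite screen.
#' @param enrichment_min_size Minimum class size for enrichment.
#' @param network A [network_config()] or list of its arguments.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L, scale = "desk", inputs = NULL,
                            out_dir = NULL, min_age = 50, min_gait = 0.6,
                            require_covariates = TRUE, min_visits = 2,
                            exclude_post_dementia = TRUE,
                            override_cuts = NULL, max_below_frac = 0.20,
                            min_fit = 30, alpha = 0.05, m_total = NULL,
                            enrichment_min_size = 2,
                            network = network_config()) {
  if (!inherits(network, "network_config"))
    network <- do.call(network_config, as.list(network))
  if (!is.null(override_cuts) && length(override_cuts) != 2)
    stop("override_cuts must be c(memory_cut, gait_cut)", call. = FALSE)
  structure(list(
    seed = as.integer(seed), scale = scale, inputs = inputs,
    out_dir = out_dir, min_age = min_age, min_gait = min_gait,
    require_covariates = require_covariates, min_visits = min_visits,
    exclude_post_dementia = exclude_post_dementia,
    override_cuts = override_cuts, max_below_frac = max_below_frac,
    min_fit = min_fit, alpha = alpha, m_total = m_total,
    enrichment_min_size = enrichment_min_size, network = network),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Unknown keys are a validation error.
#'
#' @param path `.yaml`/`.yml` or `.json` file whose keys are
#'   [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown configuration key: ", unknown[1], call. = FALSE)
  do.call(pipeline_config, cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or file input),
#' baseline filtering, slope estimation and phenotype classification, LOD
#' filtering / imputation / log2 transform, ratio computation, the
#' per-metabolite mixed-effects screen with FDR control, class enrichment,
#' and network module analysis. Every stage writes its table under
#' `out_dir`; a failing stage aborts with the stage name while earlier
#' outputs are retained. A manifest and a human-readable `report.md` are
#' written at the end. Byte-deterministic given the same config and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with `out_dir` and the main stage tables.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- out_dir %||% config$out_dir %||%
    stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list()
  emit <- function(nm, df) {
    tables[[nm]] <<- df
    write_table_auto(as.data.frame(df), file.path(out_dir, paste0(nm, ".tsv")))
  }

  truth <- NULL
  dataset <- run_stage("input", {
    if (!is.null(config$inputs)) {
      do.call(read_cohort, unname(config$inputs[c("subjects", "visits",
                                                  "panel", "panel_meta")]))
    } else {
      sim <- simulate_cohort(sim_params(config$scale,
                                        seed = child_seed(config$seed,
                                                          "simulate")))
      truth <<- sim$truth
      emit("simulation_truth_subjects", sim$truth$subjects)
      emit("simulation_truth_metabolites", sim$truth$metabolites)
      sim$dataset
    }
  })

  filt <- run_stage("filter", apply_baseline_filters(
    dataset, min_age = config$min_age, min_gait = config$min_gait,
    require_covariates = config$require_covariates))
  emit("exclusions", filt$exclusions)
  dataset <- filt$dataset

  labels <- run_stage("phenotype", {
    slopes <- estimate_annual_slopes(
      dataset, min_visits = config$min_visits,
      exclude_post_dementia = config$exclude_post_dementia)
    emit("slopes", slopes)
    cuts <- if (!is.null(config$override_cuts))
      structure(list(memory_cut = config$override_cuts[1],
                     gait_cut = config$override_cuts[2]), class = "cutpoints")
    else tertile_cutpoints(slopes)
    jsonlite::write_json(unclass(cuts), file.path(out_dir, "cutpoints.json"),
                         auto_unbox = TRUE, digits = NA)
    labels <- classify_phenotypes(slopes, cuts)
    emit("phenotypes", labels)
    labels
  })
  # subjects that could not be phenotyped leave the analytic sample
  keep <- dataset$subjects$subject_id %in% labels$subject_id
  dataset$subjects <- dataset$subjects[keep, , drop = FALSE]
  dataset$visits <- dataset$visits[
    dataset$visits$subject_id %in% labels$subject_id, , drop = FALSE]
  pk <- rownames(dataset$panel$conc) %in% dataset$visits$visit_id
  dataset$panel$conc <- dataset$panel$conc[pk, , drop = FALSE]
  dataset$panel$below_lod <- dataset$panel$below_lod[pk, , drop = FALSE]

  pre <- run_stage("preprocess", {
    lodres <- filter_by_lod(dataset$panel, config$max_below_frac)
    emit("lod_report", rbind(
      data.frame(metabolite = colnames(lodres$panel$conc),
                 below_frac = lodres$panel$below_frac, status = "kept",
                 stringsAsFactors = FALSE),
      data.frame(metabolite = lodres$excluded$metabolite,
                 below_frac = lodres$excluded$below_frac,
                 status = lodres$excluded$reason, stringsAsFactors = FALSE)))
    panel <- impute_panel(lodres$panel, seed = child_seed(config$seed, "impute"),
                          min_fit = config$min_fit)
    processed <- log2_matrix(panel)
    ratios <- if (all(unique(unlist(lapply(ratio_definitions(), unlist))) %in%
                      colnames(panel$conc)))
      compute_ratio_panel(panel$conc)
    else NULL
    list(processed = processed, ratios = ratios)
  })

  screen <- run_stage("screen", {
    screen <- screen_all(pre$processed, labels, dataset,
                         m_total = config$m_total)
    emit("screen_results", screen)
    if (!is.null(pre$ratios)) {
      emit("ratio_results",
           screen_ratios(pre$ratios, labels, dataset, alpha = config$alpha))
    }
    screen
  })

  run_stage("enrich", {
    emit("enrichment", enrich_classes(screen,
                                      min_size = config$enrichment_min_size))
    emit("significant_export", export_significant(screen))
  })

  run_stage("modules", {
    rho <- spearman_matrix(pre$processed$log2)
    A <- soft_adjacency(rho, beta = config$network$beta,
                        signed = config$network$signed)
    tom <- topological_overlap(A)
    assignment <- detect_modules(tom, config$network)
    hubs <- hub_metabolite(assignment, A)
    assignment$is_hub <- assignment$metabolite %in% hubs$hub
    emit("modules", assignment)
    if (nrow(hubs)) {
      ms <- module_scores(pre$processed$log2, assignment)
      emit("module_scores", data.frame(visit_id = rownames(ms$scores),
                                       ms$scores, check.names = FALSE))
      emit("module_lme", module_group_lme(ms$scores, labels, dataset,
                                          alpha = config$alpha))
      emit("module_summary", data.frame(
        module = hubs$module, hub = hubs$hub,
        size = as.integer(table(assignment$module)[as.character(hubs$module)]),
        pc1_var_explained = unname(ms$var_explained),
        stringsAsFactors = FALSE))
    } else {
      emit("module_summary", data.frame(module = integer(0), hub = character(0),
                                        size = integer(0),
                                        pc1_var_explained = numeric(0)))
    }
  })

  manifest <- list(
    config = config_to_list(config), seed = config$seed,
    package = "dualtraj",
    version = as.character(packageVersion("dualtraj")),
    n_subjects_analyzed = nrow(dataset$subjects),
    n_metabolites_kept = ncol(pre$processed$log2))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  make_report(out_dir)
  invisible(list(out_dir = out_dir, tables = tables, truth = truth))
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$network <- unclass(x$network)
  x$out_dir <- NULL  # run location is not part of the reproducible config
  x[!vapply(x, is.null, TRUE)]
}

md_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  cells <- vapply(df, function(col) as.character(col), character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  body <- vapply(seq_len(nrow(df)), function(i)
    paste("|", paste(cells[i, ], collapse = " | "), "|"), "")
  paste(c(header, sep, body), collapse = "\n")
}

#' Regenerate the run report from stage tables
#'
#' Builds `report.md` purely from the TSV tables in `run_dir`: phenotype
#' group sizes, the top metabolites of the discovery screen with their
#' q-values, class enrichment, ratio contrasts, and module summaries. Stages
#' whose table is absent are listed as skipped. Idempotent: regenerating
#' from the same tables yields the same report.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Path of the report, invisibly.
#' @export
make_report <- function(run_dir) {
  get_tbl <- function(nm) {
    p <- file.path(run_dir, paste0(nm, ".tsv"))
    if (file.exists(p)) read.delim(p, sep = "\t", check.names = FALSE) else NULL
  }
  lines <- c("# Dual-decline metabolomics run report", "")

  phen <- get_tbl("phenotypes")
  if (!is.null(phen)) {
    counts <- table(factor(phen$label, levels = phenotype_levels()))
    lines <- c(lines, "## Phenotype groups", "",
               md_table(data.frame(group = names(counts),
                                   n = as.integer(counts))), "")
  } else lines <- c(lines, "## Phenotype groups", "", "_stage skipped_", "")

  scr <- get_tbl("screen_results")
  if (!is.null(scr)) {
    sig <- scr[!is.na(scr$q_omnibus) & scr$q_omnibus < 0.05, , drop = FALSE]
    lines <- c(lines, "## Metabolite screen", "",
               sprintf("%d metabolites screened; %d with omnibus q < 0.05.",
                       nrow(scr), nrow(sig)), "",
               md_table(head(scr[, c("metabolite", "class", "p_omnibus",
                                     "q_omnibus", "beta_dual", "p_dual")],
                             15)), "")
  } else lines <- c(lines, "## Metabolite screen", "", "_stage skipped_", "")

  enr <- get_tbl("enrichment")
  if (!is.null(enr)) {
    lines <- c(lines, "## Class enrichment", "", md_table(enr), "")
  } else lines <- c(lines, "## Class enrichment", "", "_stage skipped_", "")

  rat <- get_tbl("ratio_results")
  if (!is.null(rat)) {
    lines <- c(lines, "## Ratio measures", "",
               md_table(rat[, c("ratio", "beta_dual", "p_dual",
                                "p_omnibus", "significant_omnibus")]), "")
  } else lines <- c(lines, "## Ratio measures", "", "_stage skipped_", "")

  mods <- get_tbl("module_summary")
  lme_mod <- get_tbl("module_lme")
  if (!is.null(mods)) {
    lines <- c(lines, "## Network modules", "",
               if (nrow(mods)) md_table(mods) else "No modules detected.", "")
    if (!is.null(lme_mod) && nrow(lme_mod))
      lines <- c(lines, md_table(lme_mod), "")
  } else lines <- c(lines, "## Network modules", "", "_stage skipped_", "")

  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
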