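# Synthetic longitudinal cohort generator with planted ground truth.
#
# The generator emulates the statistical structure the analysis assumes in an
# aging cohort: per-subject linear memory (CVLT points) and gait (m/s)
# trajectories whose annual slopes are drawn around group-specific means for
# the four phenotype groups; metabolite log2 abundances with a per-subject
# random intercept, optional planted group-by-time effects, and
# block-correlated modules driven by per-visit latent factors; and
# left-censoring at a per-metabolite limit of detection. Group membership is
# the generative primitive, so classification accuracy against the planted
# labels is measurable.

# constituent metabolites of the nine physiological ratios, with typical
# fasting plasma concentrations (uM) and Biocrates-style class labels
RATIO_CONSTITUENTS <- data.frame(
  metabolite = c("Val", "Leu", "Ile", "Phe", "Tyr", "Arg", "Orn", "Cit",
                 "hArg", "Lys", "HCys", "Met", "Hippuric acid", "Gly",
                 "Kynurenine", "Trp", "DHA", "EPA", "Pro", "Sarcosine"),
  class = c(rep("Amino acids", 8),
            "Amino acid related", "Amino acids", "Amino acid related",
            "Amino acids", "Carboxylic acids", "Amino acids",
            "Amino acid related", "Amino acids", "Fatty acids",
            "Fatty acids", "Amino acids", "Amino acid related"),
  typical_um = c(250, 140, 75, 70, 70, 80, 60, 30, 2.5, 180, 10, 25, 2.2,
                 250, 2, 60, 120, 40, 180, 1.4),
  stringsAsFactors = FALSE)

#' Simulation parameters
#'
#' Builds the parameter set for [simulate_cohort()] at one of three scales:
#' `"smoke"` (60 subjects, for fast checks), `"desk"` (200 subjects, the
#' default working scale) and `"full"` (855 subjects, the size of the cohort
#' the pipeline is designed for). Visit counts are drawn from a distribution
#' with mean about 2.7 on 2-6 visits, follow-up is capped at 12 years, and
#' group proportions default to (0.47, 0.20, 0.20, 0.13) for no decline,
#' memory decline only, gait decline only and dual decline.
#'
#' Any default can be overridden by name through `...`; unknown names are an
#' error.
#'
#' @param scale One of `"smoke"`, `"desk"`, `"full"`.
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @param ... Named overrides of any default listed below.
#' @return An object of class `sim_params`: a named list with entries
#'   `n_subjects`, `group_props`, `visit_n_probs` (named probabilities for
#'   2-6 visits), `gap_range` (years between visits), `max_followup_years`,
#'   memory/gait slope means (per group, points/yr and m/s/yr), slope and
#'   residual SDs, baseline distributions, `dementia_frac`,
#'   `n_metabolites`, `module_sizes`, `module_loading`, `met_subject_sd`,
#'   `met_resid_sd` (log2 units), `effects` (per-group named vectors of
#'   planted group-by-time slopes, log2 units/yr), `lod_quantile`,
#'   `constituents` and `seed`.
#' @export
sim_params <- function(scale = c("desk", "smoke", "full"), seed = 1L, ...) {
  scale <- match.arg(scale)
  base <- switch(scale,
    smoke = list(n_subjects = 60L, n_metabolites = 36L,
                 module_sizes = c(6L, 5L)),
    desk = list(n_subjects = 200L, n_metabolites = 80L,
                module_sizes = c(20L, 15L, 10L)),
    full = list(n_subjects = 855L, n_metabolites = 480L,
                module_sizes = c(60L, 45L, 30L)))
  p <- c(base, list(
    scale = scale,
    seed = as.integer(seed),
    group_props = c(no_decline = 0.47, memory_decline_only = 0.20,
                    gait_decline_only = 0.20, dual_decline = 0.13),
    visit_n_probs = c(`2` = 0.58, `3` = 0.24, `4` = 0.10, `5` = 0.05,
                      `6` = 0.03),
    gap_range = c(1, 2.5),
    max_followup_years = 12,
    memory_slope_mean = c(no_decline = -0.1, memory_decline_only = -1.2,
                          gait_decline_only = -0.1, dual_decline = -1.2),
    gait_slope_mean = c(no_decline = -0.005, memory_decline_only = -0.005,
                        gait_decline_only = -0.045, dual_decline = -0.045),
    memory_slope_sd = 0.35, gait_slope_sd = 0.012,
    memory_resid_sd = 2.5, gait_resid_sd = 0.06,
    memory_baseline_mean = 52, memory_baseline_sd = 11,
    gait_baseline_mean = 1.15, gait_baseline_sd = 0.2,
    age_mean = 70, age_sd = 9,
    education_mean = 17.5, education_sd = 2.7,
    prop_male = 0.47, prop_black = 0.28, prop_apoe4 = 0.26,
    entry_year_range = c(2006, 2016),
    dementia_frac = 0.05,
    module_loading = 0.6,
    met_subject_sd = 0.3,
    met_resid_sd = 0.4,
    met_mean_range = c(-1, 6),
    effects = list(
      dual_decline = c("LysoPC a C16:0" = -0.05, "LysoPC a C17:0" = -0.05,
                       "LysoPC a C18:0" = -0.05, "LysoPC a C18:1" = -0.05,
                       "LysoPC a C18:2" = -0.05,
                       "Kynurenine" = 0.04, "hArg" = -0.03)),
    lod_quantile = 0.05,
    constituents = TRUE))
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown simulation parameter: ", unknown[1], call. = FALSE)
    p[names(over)] <- over
  }
  if (!isTRUE(p$constituents)) p$effects <- p$effects %||% list()
  validate_sim_params(structure(p, class = "sim_params"))
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (abs(sum(p$group_props) - 1) > 1e-12)
    stop("group_props must sum to 1", call. = FALSE)
  sds <- c(p$memory_slope_sd, p$gait_slope_sd, p$memory_resid_sd,
           p$gait_resid_sd, p$met_subject_sd, p$met_resid_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (p$lod_quantile < 0 || p$lod_quantile >= 0.5)
    stop("lod_quantile must be in [0, 0.5)", call. = FALSE)
  n_fixed <- if (isTRUE(p$constituents)) nrow(RATIO_CONSTITUENTS) else 0L
  if (isTRUE(p$constituents) && p$n_metabolites < n_fixed)
    stop("n_metabolites must be at least ", n_fixed,
         " when ratio constituents are included", call. = FALSE)
  if (sum(p$module_sizes) > p$n_metabolites - n_fixed)
    stop("module sizes exceed the number of available metabolites",
         call. = FALSE)
  p
}

# names and classes for the non-constituent part of the panel; module
# metabolites get class-homogeneous lipid names, the background mixes
# lysophosphatidylcholines, ceramides and other quantified-panel classes
panel_naming <- function(n_free, module_sizes) {
  module <- integer(n_free)
  name <- character(n_free)
  cls <- character(n_free)
  k <- 0L
  mod_class <- c("Triglycerides", "Sphingomyelins", "Phosphatidylcholines",
                 "Cholesteryl esters", "Acylcarnitines")
  mod_stub <- c("TG", "SM", "PC ae", "CE", "AC")
  for (m in seq_along(module_sizes)) {
    idx <- k + seq_len(module_sizes[m])
    module[idx] <- m
    cls[idx] <- mod_class[(m - 1L) %% length(mod_class) + 1L]
    name[idx] <- sprintf("%s %02d:%d", mod_stub[(m - 1L) %% length(mod_stub) + 1L],
                         14L + seq_along(idx), m %% 2L)
    k <- k + module_sizes[m]
  }
  bg_names <- c("LysoPC a C16:0", "LysoPC a C17:0", "LysoPC a C18:0",
                "LysoPC a C18:1", "LysoPC a C18:2",
                "Cer(d18:1/24:0)", "Cer(d18:2/24:0)", "Cer(d16:1/24:0)",
                "Cer(d16:1/23:0)", "Cer(d18:1/22:0)",
                "Hypoxanthine", "H1", "Taurine", "Putrescine", "Spermidine")
  bg_class <- c(rep("Lysophosphatidylcholines", 5), rep("Ceramides", 5),
                "Nucleobases and related", "Hexoses", "Amino acid related",
                "Biogenic amines", "Biogenic amines")
  n_bg <- n_free - k
  if (n_bg > 0) {
    idx <- k + seq_len(n_bg)
    take <- seq_len(min(n_bg, length(bg_names)))
    name[idx[take]] <- bg_names[take]
    cls[idx[take]] <- bg_class[take]
    if (n_bg > length(bg_names)) {
      extra <- (length(bg_names) + 1L):n_bg
      name[idx[extra]] <- sprintf("PC aa C%d:%d", 28L + (extra %% 15L),
                                  extra %% 5L)
      cls[idx[extra]] <- "Phosphatidylcholines"
    }
  }
  data.frame(metabolite = name, class = cls, module = module,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a complete `cohort_dataset` (subjects, visits with concurrent memory,
#' gait and metabolomics, and a quantified metabolite panel with LOD
#' censoring) together with the `truth` used to generate it, so downstream
#' stages can be scored against planted labels, slopes, effects and module
#' memberships. Fully deterministic given `params$seed`.
#'
#' @param params A `sim_params` object from [sim_params()].
#' @return List with `dataset` (a `cohort_dataset`), `truth` (list with
#'   `subjects`: planted group, memory/gait slopes; `metabolites`: planted
#'   module and per-group time effects) and `params`.
#' @export
simulate_cohort <- function(params) {
  params <- validate_sim_params(params)
  with_preserved_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(p) {
  n <- p$n_subjects
  groups <- phenotype_levels()
  id <- sprintf("S%0*d", max(3L, nchar(n)), seq_len(n))
  group <- sample(groups, n, replace = TRUE, prob = p$group_props)

  subjects <- data.frame(
    subject_id = id,
    sex = sample(c("male", "female"), n, TRUE,
                 prob = c(p$prop_male, 1 - p$prop_male)),
    race = sample(c("White", "Black"), n, TRUE,
                  prob = c(1 - p$prop_black, p$prop_black)),
    education_years = round(rtnorm(n, p$education_mean, p$education_sd, 6, 24), 1),
    apoe4_carrier = runif(n) < p$prop_apoe4,
    baseline_age_years = rtnorm(n, p$age_mean, p$age_sd, 50, 95),
    dementia_onset_time = ifelse(runif(n) < p$dementia_frac,
                                 runif(n, 3, 10), NA_real_),
    stringsAsFactors = FALSE)

  mem_slope <- rnorm(n, p$memory_slope_mean[group], p$memory_slope_sd)
  gait_slope <- rnorm(n, p$gait_slope_mean[group], p$gait_slope_sd)
  mem_base <- rtnorm(n, p$memory_baseline_mean, p$memory_baseline_sd, 15, 75)
  gait_base <- rtnorm(n, p$gait_baseline_mean, p$gait_baseline_sd, 0.7, 1.8)
  entry_year <- runif(n, p$entry_year_range[1], p$entry_year_range[2])

  nv <- sample(as.integer(names(p$visit_n_probs)), n, TRUE, p$visit_n_probs)
  visit_rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- c(0, cumsum(runif(nv[i] - 1L, p$gap_range[1], p$gap_range[2])))
    t <- t[t <= p$max_followup_years]
    k <- length(t)
    visit_rows[[i]] <- data.frame(
      visit_id = sprintf("%s_v%d", id[i], seq_len(k)),
      subject_id = id[i],
      time_years = t,
      calendar_year = entry_year[i] + t,
      gait_speed_mps = pmax(0.05, gait_base[i] + gait_slope[i] * t +
                              rnorm(k, 0, p$gait_resid_sd)),
      memory_score = pmin(80, pmax(0, mem_base[i] + mem_slope[i] * t +
                                     rnorm(k, 0, p$memory_resid_sd))),
      stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visit_rows)
  rownames(visits) <- NULL

  # metabolite panel: constituents + module lipids + background
  if (isTRUE(p$constituents)) {
    fixed <- data.frame(metabolite = RATIO_CONSTITUENTS$metabolite,
                        class = RATIO_CONSTITUENTS$class,
                        module = 0L,
                        mu = log2(RATIO_CONSTITUENTS$typical_um),
                        stringsAsFactors = FALSE)
  } else {
    fixed <- data.frame(metabolite = character(0), class = character(0),
                        module = integer(0), mu = numeric(0))
  }
  n_free <- p$n_metabolites - nrow(fixed)
  free <- panel_naming(n_free, p$module_sizes)
  free$mu <- runif(n_free, p$met_mean_range[1], p$met_mean_range[2])
  met <- rbind(fixed, free)
  if (anyDuplicated(met$metabolite))
    met$metabolite <- make.unique(met$metabolite, sep = " #")
  n_met <- nrow(met)
  n_mod <- length(p$module_sizes)

  effect <- matrix(0, n_met, length(groups),
                   dimnames = list(met$metabolite, groups))
  for (g in names(p$effects)) {
    e <- p$effects[[g]]
    hit <- intersect(names(e), met$metabolite)
    effect[hit, g] <- e[hit]
  }

  n_vis <- nrow(visits)
  subj_idx <- match(visits$subject_id, id)
  u <- matrix(rnorm(n * n_met, 0, p$met_subject_sd), n, n_met)
  f <- if (n_mod > 0) matrix(rnorm(n_vis * n_mod), n_vis, n_mod) else NULL
  eps <- matrix(rnorm(n_vis * n_met, 0, p$met_resid_sd), n_vis, n_met)

  y <- matrix(met$mu, n_vis, n_met, byrow = TRUE) +
    u[subj_idx, , drop = FALSE] + eps
  # planted group-by-time effects: slope in log2 units/yr for the subject's group
  slope_mat <- effect[, group[subj_idx], drop = FALSE]  # n_met x n_vis
  y <- y + t(slope_mat) * visits$time_years
  if (n_mod > 0) {
    lam <- matrix(0, n_mod, n_met)
    lam[cbind(met$module[met$module > 0], which(met$module > 0))] <- p$module_loading
    y <- y + f %*% lam
  }
  conc <- 2^y
  dimnames(conc) <- list(visits$visit_id, met$metabolite)

  lod <- apply(conc, 2, function(v) {
    if (p$lod_quantile > 0) quantile(v, p$lod_quantile, type = 7)
    else min(v) / 2
  })
  meta <- data.frame(metabolite = met$metabolite, class = met$class,
                     lod = as.numeric(lod), stringsAsFactors = FALSE)

  dataset <- new_cohort_dataset(
    subjects, visits, list(meta = meta, conc = conc),
    provenance = list(simulated = TRUE, seed = p$seed, scale = p$scale))

  truth <- list(
    subjects = data.frame(subject_id = id, group = group,
                          memory_slope = mem_slope, gait_slope = gait_slope,
                          stringsAsFactors = FALSE),
    metabolites = data.frame(
      metabolite = met$metabolite, module = met$module,
      effect_memory_decline_only = effect[, "memory_decline_only"],
      effect_gait_decline_only = effect[, "gait_decline_only"],
      effect_dual_decline = effect[, "dual_decline"],
      row.names = NULL, stringsAsFactors = FALSE))
  list(dataset = dataset, truth = truth, params = p)
}
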