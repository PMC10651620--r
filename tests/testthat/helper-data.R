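# Fixture builders. Everything is constructed in code so tests carry no
# binary data.

# handcrafted 3-subject cohort: 8 visits, 3 metabolites, all concurrent
toy_cohort <- function() {
  subjects <- data.frame(
    subject_id = c("A", "B", "C"),
    sex = c("male", "female", "female"),
    race = c("White", "Black", "White"),
    education_years = c(16, 18, 12),
    apoe4_carrier = c(TRUE, FALSE, FALSE),
    baseline_age_years = c(65, 72, 58),
    dementia_onset_time = c(NA, 3.5, NA),
    stringsAsFactors = FALSE)
  visits <- data.frame(
    visit_id = c("A_v1", "A_v2", "A_v3", "B_v1", "B_v2", "B_v3", "C_v1", "C_v2"),
    subject_id = c("A", "A", "A", "B", "B", "B", "C", "C"),
    time_years = c(0, 1, 2, 0, 2, 4, 0, 1.5),
    calendar_year = c(2008, 2009, 2010, 2010, 2012, 2014, 2012, 2013.5),
    gait_speed_mps = c(1.2, 1.15, 1.1, 0.9, 0.85, 0.8, 1.4, 1.38),
    memory_score = c(50, 49, 48, 42, 40, 38, 60, 59),
    stringsAsFactors = FALSE)
  conc <- matrix(c(10, 11, 9, 8, 7, 6, 12, 13,
                   0.5, 0.6, 0.4, 0.3, 0.2, 0.25, 0.7, 0.8,
                   100, 110, 95, 90, 85, 80, 120, 125),
                 nrow = 8,
                 dimnames = list(visits$visit_id, c("M1", "M2", "M3")))
  meta <- data.frame(metabolite = c("M1", "M2", "M3"),
                     class = c("Amino acids", "Ceramides", "Hexoses"),
                     lod = c(1, 0.25, 10), stringsAsFactors = FALSE)
  new_cohort_dataset(subjects, visits, list(meta = meta, conc = conc))
}

# one-outcome-per-subject dataset around handcrafted (t, y) series
slopes_from_series <- function(series) {
  subjects <- data.frame(
    subject_id = names(series), sex = "female", race = "White",
    education_years = 12, apoe4_carrier = FALSE, baseline_age_years = 70,
    dementia_onset_time = NA_real_, stringsAsFactors = FALSE)
  visits <- do.call(rbind, lapply(names(series), function(id) {
    s <- series[[id]]
    data.frame(visit_id = sprintf("%s_v%d", id, seq_along(s$t)),
               subject_id = id, time_years = s$t,
               calendar_year = 2010 + s$t,
               gait_speed_mps = s$gait %||% rep(1, length(s$t)),
               memory_score = s$mem %||% rep(50, length(s$t)),
               stringsAsFactors = FALSE)
  }))
  conc <- matrix(1, nrow(visits), 1,
                 dimnames = list(visits$visit_id, "M1"))
  meta <- data.frame(metabolite = "M1", class = "Amino acids", lod = 0.1)
  new_cohort_dataset(subjects, visits, list(meta = meta, conc = conc))
}

# noise-free desk-scale generator settings: slopes sit exactly at the planted
# group means, so classification against midpoint cuts must be perfect
noise_free_params <- function(seed, n_subjects = 200L) {
  sim_params("desk", seed = seed, n_subjects = n_subjects,
             memory_slope_sd = 0, gait_slope_sd = 0,
             memory_resid_sd = 0, gait_resid_sd = 0,
             dementia_frac = 0)
}

midpoint_cuts <- function(params) {
  structure(list(
    memory_cut = mean(params$memory_slope_mean[c("no_decline",
                                                 "dual_decline")]),
    gait_cut = mean(params$gait_slope_mean[c("no_decline", "dual_decline")])),
    class = "cutpoints")
}

# minimal single-metabolite cohort for mixed-model simulations
lme_sim_params <- function(seed, n_subjects, effect_dual = 0) {
  eff <- if (effect_dual != 0)
    list(dual_decline = c("LysoPC a C16:0" = effect_dual))
  else list()
  sim_params("smoke", seed = seed, n_subjects = as.integer(n_subjects),
             n_metabolites = 1L, module_sizes = integer(0),
             constituents = FALSE, effects = eff,
             lod_quantile = 0, dementia_frac = 0)
}

# latent-factor correlation blocks (within-block Spearman ~ rho, between ~ 0)
block_panel <- function(seed, n_obs = 100, sizes = c(20, 15, 10), rho = 0.8) {
  lambda <- sqrt(rho / (1 - rho))
  set.seed(seed)
  cols <- list()
  truth <- integer(0)
  for (b in seq_along(sizes)) {
    f <- rnorm(n_obs)
    for (j in seq_len(sizes[b])) {
      cols[[length(cols) + 1L]] <- lambda * f + rnorm(n_obs)
      truth <- c(truth, b)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- sprintf("met%02d", seq_len(ncol(X)))
  rownames(X) <- sprintf("v%03d", seq_len(nrow(X)))
  list(X = X, truth = truth)
}

truth_labels <- function(sim) {
  data.frame(subject_id = sim$truth$subjects$subject_id,
             label = factor(sim$truth$subjects$group,
                            levels = phenotype_levels()),
             stringsAsFactors = FALSE)
}
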