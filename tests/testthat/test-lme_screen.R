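balanced_frame <- function(n_per_group = 2, times = c(-2, 0)) {
  groups <- phenotype_levels()
  subj <- paste0("s", seq_len(n_per_group * length(groups)))
  grp <- rep(groups, each = n_per_group)
  data.frame(
    visit_id = paste0(rep(subj, each = length(times)), "_v",
                      seq_along(times)),
    subject_id = rep(subj, each = length(times)),
    time = rep(times, length(subj)),
    group = factor(rep(grp, each = length(times)),
                   levels = phenotype_levels()),
    stringsAsFactors = FALSE)
}

test_that("time anchoring puts the latest metabolomics visit at 0 and is idempotent", {
  d <- slopes_from_series(list(s1 = list(t = c(0, 4, 8)),
                               s2 = list(t = 0)))
  a <- anchor_time(d)
  expect_equal(a$visits$time_years[a$visits$subject_id == "s1"],
               c(-8, -4, 0))
  expect_equal(a$visits$time_years[a$visits$subject_id == "s2"], 0)
  expect_equal(anchor_time(a)$visits, a$visits)
  # dementia onset lives on the same axis and shifts with it
  d$subjects$dementia_onset_time <- c(6, NA)
  expect_equal(anchor_time(d)$subjects$dementia_onset_time, c(-2, NA))
})

test_that("REML fixed effects equal the closed-form GLS solution on a balanced design", {
  # balanced random-intercept designs: GLS = OLS for the fixed effects,
  # regardless of the variance components
  fr <- balanced_frame(n_per_group = 3)
  set.seed(52)
  u <- rnorm(length(unique(fr$subject_id)), 0, 0.7)
  y <- 1 + 0.3 * fr$time + 0.5 * (fr$group == "dual_decline") +
    u[as.integer(factor(fr$subject_id))] + rnorm(nrow(fr), 0, 0.4)
  fit <- fit_metabolite_lme(y, fr, covariates = character(0))
  ols <- lm(y ~ group * time, data = fr)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("large-sample fits recover planted interaction effects within 3 SE", {
  sim <- simulate_cohort(lme_sim_params(seed = 61, n_subjects = 300,
                                        effect_dual = 0.1))
  ds <- anchor_time(sim$dataset)
  fr <- build_screen_frame(ds, truth_labels(sim))
  y <- log2(ds$panel$conc[match(fr$visit_id, rownames(ds$panel$conc)), 1])
  fit <- fit_metabolite_lme(y, fr)
  ct <- pairwise_longitudinal_contrast(fit, "dual_decline")
  expect_lt(abs(ct$beta - 0.1), 3 * ct$se)
  expect_true(fit$converged)
})

test_that("a constant response yields a degenerate all-zero fit", {
  fr <- balanced_frame()
  fit <- fit_metabolite_lme(rep(0, nrow(fr)), fr, covariates = character(0))
  expect_true(fit$degenerate)
  expect_true(all(fit$beta == 0))
})

test_that("contrasts are invariant to adding a constant to the response", {
  fr <- balanced_frame(n_per_group = 4)
  set.seed(9)
  y <- rnorm(nrow(fr))
  f1 <- fit_metabolite_lme(y, fr, covariates = character(0))
  f2 <- fit_metabolite_lme(y + 100, fr, covariates = character(0))
  c1 <- pairwise_longitudinal_contrast(f1, "dual_decline")
  c2 <- pairwise_longitudinal_contrast(f2, "dual_decline")
  expect_equal(c1$beta, c2$beta, tolerance = 1e-6)
  expect_equal(c1$p, c2$p, tolerance = 1e-6)
})

test_that("group-by-time estimates are invariant to covariate centering", {
  sim <- simulate_cohort(lme_sim_params(seed = 77, n_subjects = 80))
  ds <- anchor_time(sim$dataset)
  fr <- build_screen_frame(ds, truth_labels(sim))
  y <- log2(ds$panel$conc[match(fr$visit_id, rownames(ds$panel$conc)), 1])
  f1 <- fit_metabolite_lme(y, fr)
  fr2 <- fr
  for (v in c("baseline_age", "education", "baseline_gait", "baseline_memory"))
    fr2[[v]] <- fr2[[v]] - mean(fr2[[v]])
  f2 <- fit_metabolite_lme(y, fr2)
  nm <- grep(":time$", names(f1$beta), value = TRUE)
  expect_equal(f1$beta[nm], f2$beta[nm], tolerance = 1e-5)
})

test_that("the omnibus Wald test follows its contract on constructed fits", {
  k <- 6
  nm <- c(paste0("group", phenotype_levels()[-1]),
          paste0("group", phenotype_levels()[-1], ":time"))
  fit <- structure(list(beta = setNames(rep(0, k), nm),
                        vcov = diag(k), group_levels = phenotype_levels(),
                        converged = TRUE, degenerate = FALSE),
                   class = "metab_lme")
  expect_equal(omnibus_group_test(fit), 1)
  fit$beta <- setNames(rep(0, 3), nm[1:3])
  fit$vcov <- diag(3)
  expect_error(omnibus_group_test(fit), "group and group-by-time")
})

test_that("requesting a contrast for an absent group is an error", {
  fr <- balanced_frame()
  set.seed(3)
  fit <- fit_metabolite_lme(rnorm(nrow(fr)), fr, covariates = character(0))
  expect_error(pairwise_longitudinal_contrast(fit, "not_a_group"))
})

test_that("step-up adjustment matches brute force, handles ties, subsets and NAs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(c(0.5, 0.5, 0.001)), c(0.5, 0.5, 0.003))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, 0.2), m_total = 1), "m_total")
  expect_equal(bh_adjust(c(0.2, NA, 0.01), m_total = 10),
               c(1, NA, 0.1))

  set.seed(88)
  for (r in 1:50) {
    n <- sample(1:8, 1)
    p <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    m <- n + sample(0:5, 1)
    q <- bh_adjust(p, m)
    expect_equal(q, bf_bh(p, m))
    expect_equal(q, p.adjust(p, "BH", n = m))
  }
})

test_that("a printed discovery subset is adjusted against its full family size", {
  ref <- read.delim(system.file("extdata", "discovery_pvalues_m461.tsv",
                                package = "dualtraj"))
  q <- bh_adjust(ref$p_omnibus, m_total = 461)
  expect_equal(q[2], 2.08e-05, tolerance = 0.005)
})

test_that("screen_all screens every metabolite, applies BH per family and ranks planted effects", {
  eff <- list(dual_decline = c("LysoPC a C16:0" = 0.15,
                               "LysoPC a C17:0" = 0.15,
                               "LysoPC a C18:0" = -0.15))
  sim <- simulate_cohort(sim_params(
    "smoke", seed = 301, n_subjects = 200L, n_metabolites = 20L,
    module_sizes = integer(0), constituents = FALSE, effects = eff,
    lod_quantile = 0, dementia_frac = 0))
  flt <- filter_by_lod(sim$dataset$panel)
  processed <- log2_matrix(flt$panel)
  labels <- truth_labels(sim)
  scr <- screen_all(processed, labels, sim$dataset)
  expect_equal(nrow(scr), 20)
  expect_equal(sort(scr$q_dual), sort(bf_bh(scr$p_dual, sum(!is.na(scr$p_dual)))))
  top5 <- scr$metabolite[order(scr$p_dual)][1:5]
  expect_true(all(names(eff$dual_decline) %in% top5))
})

test_that("an all-null panel yields no q < 0.05 discoveries", {
  sim <- simulate_cohort(sim_params(
    "smoke", seed = 302, n_subjects = 120L, n_metabolites = 30L,
    module_sizes = integer(0), constituents = FALSE, effects = list(),
    lod_quantile = 0, dementia_frac = 0))
  processed <- log2_matrix(filter_by_lod(sim$dataset$panel)$panel)
  scr <- screen_all(processed, truth_labels(sim), sim$dataset)
  expect_equal(sum(scr$q_omnibus < 0.05, na.rm = TRUE), 0)
  expect_equal(sum(scr$q_dual < 0.05, na.rm = TRUE), 0)
})

test_that("ratio screening reports raw p-values with a significance flag", {
  sim <- simulate_cohort(sim_params("smoke", seed = 303, n_subjects = 100L,
                                    dementia_frac = 0))
  panel <- impute_panel(filter_by_lod(sim$dataset$panel)$panel, seed = 1)
  ratios <- compute_ratio_panel(panel$conc)
  rs <- screen_ratios(ratios, truth_labels(sim), sim$dataset)
  expect_equal(nrow(rs), 9)
  expect_false("q_dual" %in% names(rs))
  expect_type(rs$significant_omnibus, "logical")
})
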