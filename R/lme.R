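# Per-metabolite longitudinal screening: linear mixed-effects models with a
# random subject intercept, regressing each log2 metabolite (or log2 ratio)
# on phenotype group, time, and group-by-time interactions, adjusted for
# baseline age, sex, race, education, APOE e4, baseline gait and memory, and
# calendar year. Time is anchored so each subject's most recent metabolomics
# visit is 0 and earlier visits are negative years.

DEFAULT_COVARIATES <- c("baseline_age", "sex", "race", "education", "apoe4",
                        "baseline_gait", "baseline_memory", "calendar_c")

#' Anchor the time axis at the most recent metabolomics visit
#'
#' Per subject, subtracts the time of the latest visit with metabolomics from
#' all visit times (and from the dementia onset time, which lives on the same
#' axis), so time 0 is the anchor and earlier visits are negative years.
#' Idempotent.
#'
#' @param dataset A `cohort_dataset` in which every subject has at least one
#'   metabolomics visit.
#' @return The dataset with shifted `time_years` (and `dementia_onset_time`).
#' @export
anchor_time <- function(dataset) {
  met_visits <- dataset$visits[
    dataset$visits$visit_id %in% rownames(dataset$panel$conc), , drop = FALSE]
  anchor <- tapply(met_visits$time_years, met_visits$subject_id, max)
  missing_subj <- setdiff(dataset$subjects$subject_id, names(anchor))
  if (length(missing_subj))
    stop("subject without a metabolomics visit: ", missing_subj[1],
         call. = FALSE)
  shift <- anchor[dataset$visits$subject_id]
  dataset$visits$time_years <- dataset$visits$time_years - as.numeric(shift)
  s_shift <- anchor[dataset$subjects$subject_id]
  dataset$subjects$dementia_onset_time <-
    dataset$subjects$dementia_onset_time - as.numeric(s_shift)
  dataset
}

#' Build the per-visit model frame for metabolite screening
#'
#' One row per metabolomics visit with the anchored time, the phenotype group
#' (reference `no_decline`), and subject-level covariates: age, gait and
#' memory at the baseline visit, sex, race (reference = largest level),
#' education, APOE e4 carrier status, and the calendar year of the anchor
#' visit centered at its sample mean.
#'
#' @param dataset An anchored `cohort_dataset` (see [anchor_time()]).
#' @param labels Data frame from [classify_phenotypes()]; subjects without a
#'   label are dropped.
#' @return Data frame keyed by `visit_id`, in panel row order.
#' @export
build_screen_frame <- function(dataset, labels) {
  base <- find_baseline(dataset)
  v <- dataset$visits
  pv <- rownames(dataset$panel$conc)
  df <- v[match(pv, v$visit_id), , drop = FALSE]
  si <- match(df$subject_id, dataset$subjects$subject_id)
  bi <- match(df$subject_id, base$subject_id)
  li <- match(df$subject_id, labels$subject_id)

  race <- dataset$subjects$race[si]
  race_ref <- names(sort(table(race), decreasing = TRUE))[1]
  anchor_cal <- df$calendar_year - df$time_years  # calendar year at time 0

  out <- data.frame(
    visit_id = df$visit_id,
    subject_id = df$subject_id,
    time = df$time_years,
    group = factor(as.character(labels$label[li]),
                   levels = phenotype_levels()),
    baseline_age = base$age_at_baseline[bi],
    sex = factor(dataset$subjects$sex[si], levels = c("female", "male")),
    race = factor(race, levels = c(race_ref, setdiff(unique(race), race_ref))),
    education = dataset$subjects$education_years[si],
    apoe4 = as.numeric(dataset$subjects$apoe4_carrier[si]),
    baseline_gait = base$baseline_gait[bi],
    baseline_memory = base$baseline_memory[bi],
    stringsAsFactors = FALSE)
  out$calendar_c <- anchor_cal - mean(anchor_cal[!is.na(li)], na.rm = TRUE)
  out <- out[!is.na(out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit one longitudinal mixed-effects model
#'
#' REML fit of `response ~ group * time + covariates + (1 | subject)` via
#' `lme4::lmer`. The design matrix must be full rank after dropping empty
#' factor levels; otherwise the aliased columns are reported. A constant
#' response is returned as a degenerate fit with all coefficients zero rather
#' than an optimizer failure.
#'
#' @param response Numeric vector aligned with `frame` rows; `NA`s drop the
#'   visit.
#' @param frame Model frame from [build_screen_frame()].
#' @param covariates Covariate column names (default all of
#'   age/sex/race/education/APOE/baseline gait/baseline memory/calendar).
#' @param reml Use REML (default `TRUE`).
#' @param base_fit Optional previous `metab_lme` fit with the same design and
#'   missingness pattern, reused via `lme4::refit` for speed.
#' @return Object of class `metab_lme`: `beta` (fixed effects), `vcov`,
#'   `converged`, `degenerate`, `n_obs`, `n_subjects`, `group_levels`, and
#'   the underlying `model`.
#' @export
fit_metabolite_lme <- function(response, frame,
                               covariates = intersect(DEFAULT_COVARIATES,
                                                      names(frame)),
                               reml = TRUE, base_fit = NULL) {
  stopifnot(length(response) == nrow(frame))
  dat <- frame
  dat$.y <- as.numeric(response)
  used <- c(".y", "group", "time", "subject_id", covariates)
  dat <- dat[complete.cases(dat[, used, drop = FALSE]), used, drop = FALSE]
  dat <- droplevels(dat)

  nv <- table(dat$subject_id)
  if (nrow(dat) < 4 || sum(nv >= 2) < 2)
    stop("need at least 2 subjects with at least 2 visits", call. = FALSE)

  fixed_rhs <- paste(c("group * time", covariates), collapse = " + ")
  fixed_formula <- as.formula(paste(".y ~", fixed_rhs))
  X <- model.matrix(fixed_formula, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  if (sd(dat$.y) == 0) {
    beta <- setNames(rep(0, ncol(X)), colnames(X))
    return(structure(list(model = NULL, beta = beta,
                          vcov = matrix(NA_real_, ncol(X), ncol(X),
                                        dimnames = list(colnames(X),
                                                        colnames(X))),
                          converged = TRUE, degenerate = TRUE,
                          n_obs = nrow(dat),
                          n_subjects = length(unique(dat$subject_id)),
                          group_levels = levels(dat$group)),
                     class = "metab_lme"))
  }

  formula <- as.formula(paste(".y ~", fixed_rhs, "+ (1 | subject_id)"))
  converged <- TRUE
  handler <- function(w) {
    if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
      converged <<- FALSE
    invokeRestart("muffleWarning")
  }
  mod <- NULL
  if (!is.null(base_fit) && !is.null(base_fit$model) &&
      !anyNA(response) && base_fit$n_obs == nrow(dat)) {
    mod <- tryCatch(
      withCallingHandlers(
        suppressMessages(refit(base_fit$model, newresp = dat$.y)),
        warning = handler),
      error = function(e) NULL)
  }
  if (is.null(mod)) {
    mod <- withCallingHandlers(
      suppressMessages(
        lmer(formula, data = dat, REML = reml,
             control = lmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore"))),
      warning = handler)
  }
  structure(list(model = mod, beta = fixef(mod),
                 vcov = as.matrix(vcov(mod)),
                 converged = converged, degenerate = FALSE,
                 n_obs = nrow(dat),
                 n_subjects = length(unique(dat$subject_id)),
                 group_levels = levels(dat$group)),
            class = "metab_lme")
}

group_term_indices <- function(fit) {
  nm <- names(fit$beta)
  main <- grep("^group[^:]*$", nm)
  inter <- grep("^group.+:time$|^time:group", nm)
  list(main = main, inter = inter)
}

#' Joint Wald test of all group differences
#'
#' Chi-square Wald test that every group main-effect and group-by-time
#' interaction coefficient is zero (6 degrees of freedom with four groups),
#' i.e. a single omnibus p-value covering both cross-sectional and
#' longitudinal group differences.
#'
#' @param fit A `metab_lme` fit containing the group terms.
#' @return The omnibus p-value (`NA` for degenerate or non-converged fits).
#' @export
omnibus_group_test <- function(fit) {
  idx <- group_term_indices(fit)
  k <- length(fit$group_levels) - 1L
  if (length(idx$main) != k || length(idx$inter) != k)
    stop("model does not contain the expected group and group-by-time terms",
         call. = FALSE)
  if (isTRUE(fit$degenerate) || !isTRUE(fit$converged)) return(NA_real_)
  j <- c(idx$main, idx$inter)
  b <- fit$beta[j]
  V <- fit$vcov[j, j, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(V, b))
  pchisq(W, df = length(j), lower.tail = FALSE)
}

#' Pairwise longitudinal contrast against no decline
#'
#' Wald z test on the single group-by-time interaction coefficient for one
#' declining group versus the `no_decline` reference: the estimate is the
#' additional annual change (log2 units/yr for a log2 response) in that group.
#'
#' @param fit A `metab_lme` fit.
#' @param group One of `"memory_decline_only"`, `"gait_decline_only"`,
#'   `"dual_decline"`.
#' @return List with `beta`, `se`, `z`, `p`.
#' @export
pairwise_longitudinal_contrast <- function(fit, group) {
  group <- match.arg(group, phenotype_levels()[-1])
  nm <- paste0("group", group, ":time")
  if (!nm %in% names(fit$beta))
    stop("group '", group, "' is absent from the fitted model", call. = FALSE)
  if (isTRUE(fit$degenerate))
    return(list(beta = 0, se = NA_real_, z = NA_real_, p = NA_real_))
  b <- unname(fit$beta[nm])
  se <- sqrt(fit$vcov[nm, nm])
  z <- b / se
  list(beta = b, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} (m_total * p_(j) / j)`, capped at 1 and mapped back
#' to input order; tied p-values share a q. `m_total` may exceed the number
#' of supplied p-values to adjust a printed subset against the full testing
#' family it came from. `NA`s are passed through and do not count toward the
#' default family size.
#'
#' @param pvalues Numeric vector in \[0, 1\] (`NA` allowed).
#' @param m_total Family size (default: number of non-`NA` p-values).
#' @return Vector of q-values, same length and order as `pvalues`.
#' @export
bh_adjust <- function(pvalues, m_total = NULL) {
  p <- pvalues[!is.na(pvalues)]
  if (any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m_total <- m_total %||% length(p)
  if (m_total < length(p))
    stop("m_total must be at least the number of p-values", call. = FALSE)
  out <- rep(NA_real_, length(pvalues))
  if (!length(p)) return(out)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m_total * p[o] / seq_along(p))))
  q <- numeric(length(p))
  q[o] <- pmin(1, q_sorted)
  out[!is.na(pvalues)] <- q
  out
}

#' Screen every metabolite with the longitudinal mixed model
#'
#' Fits one mixed model per metabolite of the processed panel, extracts the
#' omnibus p-value and the three pairwise group-by-time contrasts, and
#' applies Benjamini-Hochberg adjustment within each family across all
#' converged metabolites (the family size defaults to that count, matching
#' a discovery screen over all kept metabolites). Non-converged fits get `NA`
#' p-values and do not count toward the family size.
#'
#' @param processed A `processed_panel` from [log2_matrix()].
#' @param labels Phenotype labels from [classify_phenotypes()].
#' @param dataset The (filtered) `cohort_dataset`; anchored internally.
#' @param covariates Covariate set, as in [fit_metabolite_lme()].
#' @param m_total Optional explicit BH family size.
#' @return Data frame with one row per metabolite: class, sample sizes,
#'   `beta`/`se`/`p` for each declining group's interaction, `p_omnibus`,
#'   and q-value columns `q_omnibus`, `q_memory`, `q_gait`, `q_dual`.
#' @export
screen_all <- function(processed, labels, dataset,
                       covariates = DEFAULT_COVARIATES, m_total = NULL) {
  stopifnot(inherits(processed, "processed_panel"))
  dataset <- anchor_time(dataset)
  frame <- build_screen_frame(dataset, labels)
  Y <- processed$log2[match(frame$visit_id, rownames(processed$log2)), ,
                      drop = FALSE]
  mets <- colnames(Y)
  base_fit <- NULL
  rows <- vector("list", length(mets))
  for (j in seq_along(mets)) {
    fit <- tryCatch(
      fit_metabolite_lme(Y[, j], frame, covariates = covariates,
                         base_fit = base_fit),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[j]] <- data.frame(
        metabolite = mets[j], converged = FALSE, n_obs = NA_integer_,
        n_subjects = NA_integer_,
        beta_memory = NA_real_, se_memory = NA_real_, p_memory = NA_real_,
        beta_gait = NA_real_, se_gait = NA_real_, p_gait = NA_real_,
        beta_dual = NA_real_, se_dual = NA_real_, p_dual = NA_real_,
        p_omnibus = NA_real_, stringsAsFactors = FALSE)
      next
    }
    if (is.null(base_fit) && !is.null(fit$model) && !anyNA(Y[, j]))
      base_fit <- fit
    cm <- pairwise_longitudinal_contrast(fit, "memory_decline_only")
    cg <- pairwise_longitudinal_contrast(fit, "gait_decline_only")
    cd <- pairwise_longitudinal_contrast(fit, "dual_decline")
    rows[[j]] <- data.frame(
      metabolite = mets[j], converged = fit$converged, n_obs = fit$n_obs,
      n_subjects = fit$n_subjects,
      beta_memory = cm$beta, se_memory = cm$se, p_memory = cm$p,
      beta_gait = cg$beta, se_gait = cg$se, p_gait = cg$p,
      beta_dual = cd$beta, se_dual = cd$se, p_dual = cd$p,
      p_omnibus = omnibus_group_test(fit), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$class <- processed$meta$class[match(res$metabolite,
                                          processed$meta$metabolite)]
  for (fam in c(omnibus = "p_omnibus", memory = "p_memory",
                gait = "p_gait", dual = "p_dual")) {
    m <- m_total %||% sum(!is.na(res[[fam]]))
    res[[sub("p_", "q_", fam)]] <- bh_adjust(res[[fam]], m)
  }
  res <- res[, c("metabolite", "class", "converged", "n_obs", "n_subjects",
                 "beta_memory", "se_memory", "p_memory", "q_memory",
                 "beta_gait", "se_gait", "p_gait", "q_gait",
                 "beta_dual", "se_dual", "p_dual", "q_dual",
                 "p_omnibus", "q_omnibus")]
  res <- res[order(res$p_omnibus), ]
  rownames(res) <- NULL
  res
}

#' Screen the nine ratio measures
#'
#' Log2-transforms each ratio and fits the same longitudinal mixed model as
#' for individual metabolites. Per the small, pre-specified size of this
#' family, significance is judged at raw `p < alpha` without FDR adjustment.
#'
#' @param ratios Matrix from [compute_ratio_panel()] (visits x ratios).
#' @param labels,dataset,covariates As in [screen_all()].
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame with per-ratio contrasts, omnibus p, and significance
#'   flags.
#' @export
screen_ratios <- function(ratios, labels, dataset,
                          covariates = DEFAULT_COVARIATES, alpha = 0.05) {
  dataset <- anchor_time(dataset)
  frame <- build_screen_frame(dataset, labels)
  R <- ratios[match(frame$visit_id, rownames(ratios)), , drop = FALSE]
  rows <- vector("list", ncol(R))
  for (j in seq_len(ncol(R))) {
    y <- suppressWarnings(log2(R[, j]))
    y[!is.finite(y)] <- NA_real_
    fit <- tryCatch(fit_metabolite_lme(y, frame, covariates = covariates),
                    error = function(e) NULL)
    if (is.null(fit)) next
    cm <- pairwise_longitudinal_contrast(fit, "memory_decline_only")
    cg <- pairwise_longitudinal_contrast(fit, "gait_decline_only")
    cd <- pairwise_longitudinal_contrast(fit, "dual_decline")
    p_omni <- omnibus_group_test(fit)
    rows[[j]] <- data.frame(
      ratio = colnames(R)[j], n_obs = fit$n_obs,
      beta_memory = cm$beta, p_memory = cm$p,
      beta_gait = cg$beta, p_gait = cg$p,
      beta_dual = cd$beta, p_dual = cd$p,
      p_omnibus = p_omni,
      significant_omnibus = !is.na(p_omni) && p_omni < alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
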