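# Metabolite preprocessing: LOD-based filtering, left-censored imputation,
# log2 transformation, and the nine physiological ratio measures.

#' Exclude metabolites by below-LOD fraction
#'
#' A metabolite is excluded iff its fraction of below-LOD values among
#' non-missing measurements is strictly greater than `max_below_frac`
#' (default 20%; exactly 20% is kept). Metabolites with no non-missing values
#' are excluded with reason `"all missing"`. Idempotent.
#'
#' @param panel Panel list (`meta`, `conc`, `below_lod`) as held in a
#'   `cohort_dataset`.
#' @param max_below_frac Maximum tolerated below-LOD fraction (default 0.20).
#' @return List with `panel` (kept metabolites) and `excluded` (data frame
#'   `metabolite`, `below_frac`, `reason`).
#' @export
filter_by_lod <- function(panel, max_below_frac = 0.20) {
  n_obs <- colSums(!is.na(panel$conc))
  n_below <- colSums(panel$below_lod & !is.na(panel$conc))
  frac <- ifelse(n_obs > 0, n_below / n_obs, NA_real_)
  all_missing <- n_obs == 0
  drop <- all_missing | (!all_missing & frac > max_below_frac)

  excluded <- data.frame(
    metabolite = colnames(panel$conc)[drop],
    below_frac = frac[drop],
    reason = ifelse(all_missing[drop], "all missing",
                    sprintf("below-LOD fraction %.3f > %.2f",
                            frac[drop], max_below_frac)),
    row.names = NULL, stringsAsFactors = FALSE)
  kept <- panel
  kept$conc <- panel$conc[, !drop, drop = FALSE]
  kept$below_lod <- panel$below_lod[, !drop, drop = FALSE]
  kept$meta <- panel$meta[!drop, , drop = FALSE]
  rownames(kept$meta) <- NULL
  kept$below_frac <- frac[!drop]
  list(panel = kept, excluded = excluded)
}

#' Impute below-LOD values of one metabolite
#'
#' Left-censored imputation: a lognormal density (quadratic log-density on the
#' log scale) is fitted to the censored sample by maximum likelihood -- each
#' observed value contributes its density, each below-LOD value the censored
#' mass below the LOD -- and every below-LOD value is replaced by an
#' independent draw from the fitted distribution truncated to (0, LOD).
#' Draws are deterministic given `seed` and never touch observed values.
#'
#' With fewer than `min_fit` observed values the fit is unreliable and the
#' deterministic fallback LOD/sqrt(2) is substituted with a warning.
#'
#' @param values Numeric vector of concentrations (one metabolite, all
#'   visits); may contain `NA`.
#' @param lod Limit of detection (> 0), same units as `values`.
#' @param seed Integer seed for the truncated draws.
#' @param below Logical mask of censored entries; defaults to
#'   `values < lod`.
#' @param min_fit Minimum observed (above-LOD) values required to fit the
#'   density (default 30).
#' @return `values` with censored entries replaced; all imputed values lie
#'   strictly in (0, LOD).
#' @export
impute_below_lod <- function(values, lod, seed = 1L, below = NULL,
                             min_fit = 30) {
  stopifnot(is.numeric(values), length(lod) == 1, lod > 0)
  if (is.null(below)) below <- !is.na(values) & values < lod
  if (!any(below)) return(values)
  obs <- values[!below & !is.na(values)]
  n_below <- sum(below)

  fallback <- function(msg) {
    warning("below-LOD imputation fell back to LOD/sqrt(2): ", msg,
            call. = FALSE)
    values[below] <- lod / sqrt(2)
    values
  }
  if (length(obs) < min_fit)
    return(fallback(sprintf("only %d observed values (< %d)",
                            length(obs), min_fit)))

  cens <- data.frame(
    left = c(obs, rep(NA_real_, n_below)),
    right = c(obs, rep(lod, n_below)))
  fit <- try(suppressWarnings(
    fitdistrplus::fitdistcens(cens, "lnorm")), silent = TRUE)
  if (inherits(fit, "try-error") || any(!is.finite(fit$estimate)))
    return(fallback("censored density fit did not converge"))
  ml <- fit$estimate[["meanlog"]]
  sl <- fit$estimate[["sdlog"]]

  draws <- with_preserved_seed(seed, {
    u <- runif(n_below)
    qlnorm(u * plnorm(lod, ml, sl), ml, sl)
  })
  # guard the open-interval contract against numerical round-off at the cap
  draws <- pmin(pmax(draws, lod * 1e-12), lod * (1 - 1e-12))
  values[below] <- draws
  values
}

#' Impute below-LOD values across a panel
#'
#' Applies [impute_below_lod()] to every metabolite, pooled across visits,
#' with a deterministic per-metabolite child seed.
#'
#' @param panel Panel list (`meta`, `conc`, `below_lod`).
#' @param seed Integer base seed.
#' @param min_fit Passed to [impute_below_lod()].
#' @return The panel with `conc` imputed and `imputed` set to the censored
#'   mask that was filled in.
#' @export
impute_panel <- function(panel, seed = 1L, min_fit = 30) {
  conc <- panel$conc
  for (j in seq_len(ncol(conc))) {
    conc[, j] <- impute_below_lod(
      conc[, j], panel$meta$lod[j],
      seed = child_seed(seed, paste0("impute:", colnames(conc)[j])),
      below = panel$below_lod[, j], min_fit = min_fit)
  }
  panel$conc <- conc
  panel$imputed <- panel$below_lod
  panel
}

#' Log2-transform a panel
#'
#' Elementwise log2 of the (post-imputation) concentration matrix. All values
#' must be strictly positive; a non-positive value is an error naming the
#' metabolite and visit.
#'
#' @param panel Panel list with positive `conc`.
#' @return A `processed_panel` list: `log2` (visits x metabolites), `meta`,
#'   `imputed` mask, `below_frac` per metabolite.
#' @export
log2_matrix <- function(panel) {
  conc <- panel$conc
  bad <- which(!is.na(conc) & conc <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive concentration for metabolite '",
         colnames(conc)[bad[1, 2]], "' at visit '",
         rownames(conc)[bad[1, 1]], "'", call. = FALSE)
  structure(list(
    log2 = log2(conc),
    meta = panel$meta,
    imputed = panel$imputed %||% (panel$below_lod & FALSE),
    below_frac = panel$below_frac %||%
      colSums(panel$below_lod) / pmax(1, colSums(!is.na(conc)))),
    class = "processed_panel")
}

#' Definitions of the nine metabolite ratio measures
#'
#' Each ratio is a sum-of-constituents over sum-of-constituents on the
#' concentration scale: the Fischer ratio (branched-chain over aromatic amino
#' acids), the global arginine bioavailability ratio (GABR), homoarginine,
#' homocysteine, hippuric-acid and sarcosine synthesis ratios, IDO activity
#' (kynurenine/tryptophan), DHA/EPA and proline/citrulline.
#'
#' @param aromatic Constituents of the Fischer-ratio denominator; the
#'   classical definition (default) is phenylalanine + tyrosine.
#' @return Named list; each element has `num` and `den` constituent vectors.
#' @export
ratio_definitions <- function(aromatic = c("Phe", "Tyr")) {
  list(
    fischer_ratio = list(num = c("Val", "Leu", "Ile"), den = aromatic),
    gabr = list(num = "Arg", den = c("Orn", "Cit")),
    harg_synthesis = list(num = "hArg", den = c("Arg", "Lys")),
    hcys_synthesis = list(num = "HCys", den = "Met"),
    hippuric_acid_synthesis = list(num = "Hippuric acid", den = "Gly"),
    ido_activity = list(num = "Kynurenine", den = "Trp"),
    dha_epa_ratio = list(num = "DHA", den = "EPA"),
    pro_cit_ratio = list(num = "Pro", den = "Cit"),
    sarcosine_synthesis = list(num = "Sarcosine", den = "Gly"))
}

#' Compute the nine-ratio panel
#'
#' Ratios are computed per visit on the concentration scale (before any log
#' transform); downstream modeling log2-transforms them exactly like
#' metabolites. A zero or missing denominator yields `NA`, never infinity.
#'
#' @param conc Concentration matrix (visits x metabolites) with metabolite
#'   column names, or a panel list with a `conc` element.
#' @param aromatic Passed to [ratio_definitions()].
#' @return Matrix visits x 9 ratios, rownames preserved.
#' @export
compute_ratio_panel <- function(conc, aromatic = c("Phe", "Tyr")) {
  if (is.list(conc) && !is.null(conc$conc)) conc <- conc$conc
  defs <- ratio_definitions(aromatic)
  needed <- unique(unlist(lapply(defs, unlist)))
  miss <- setdiff(needed, colnames(conc))
  if (length(miss))
    stop("ratio constituent metabolite(s) missing from panel: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- matrix(NA_real_, nrow(conc), length(defs),
                dimnames = list(rownames(conc), names(defs)))
  for (r in names(defs)) {
    num <- rowSums(conc[, defs[[r]]$num, drop = FALSE])
    den <- rowSums(conc[, defs[[r]]$den, drop = FALSE])
    val <- num / den
    val[!is.finite(val)] <- NA_real_
    out[, r] <- val
  }
  out
}
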