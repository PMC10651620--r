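# Weighted correlation-network module analysis: Spearman correlations,
# signed soft-thresholded adjacency, topological overlap, average-linkage
# hierarchical module detection, hub metabolites (highest intramodular
# connectivity), and eigen-metabolite (PC1) module scores.

#' Network configuration
#'
#' @param beta Soft-thresholding power (positive integer, default 6, the
#'   conventional choice for signed networks).
#' @param signed Signed network (default `TRUE`): negatively correlated
#'   metabolites get near-zero adjacency.
#' @param cut_height Static cut height on the 1 - TOM dissimilarity tree, in
#'   (0, 1) (default 0.9).
#' @param min_module_size Smaller clusters are left unassigned (default 5).
#' @return List of class `network_config`.
#' @export
network_config <- function(beta = 6, signed = TRUE, cut_height = 0.9,
                           min_module_size = 5) {
  stopifnot(beta >= 1, cut_height > 0, cut_height < 1, min_module_size >= 2)
  structure(list(beta = beta, signed = signed, cut_height = cut_height,
                 min_module_size = min_module_size),
            class = "network_config")
}

#' Spearman correlation matrix of a log2 panel
#'
#' Pairwise-complete Spearman correlations between metabolites. Constant
#' metabolites (undefined rank correlation) and pairs with fewer than 3
#' shared observations are errors.
#'
#' @param log2_panel Numeric matrix, visits x metabolites.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(log2_panel) {
  sds <- apply(log2_panel, 2, sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    stop("constant metabolite has undefined correlation: '",
         colnames(log2_panel)[which(sds == 0)[1]], "'", call. = FALSE)
  obs <- !is.na(log2_panel)
  shared <- crossprod(obs)
  if (any(shared < 3))
    stop("fewer than 3 paired observations for some metabolite pair",
         call. = FALSE)
  rho <- cor(log2_panel, method = "spearman", use = "pairwise.complete.obs")
  diag(rho) <- 1
  rho
}

#' Soft-thresholded adjacency
#'
#' Signed adjacency `((1 + rho) / 2)^beta` or unsigned `|rho|^beta`, with a
#' zero diagonal for connectivity computations.
#'
#' @param rho Correlation matrix.
#' @param beta Soft power.
#' @param signed Signed transform (default `TRUE`).
#' @return Adjacency matrix with entries in \[0, 1\] and zero diagonal.
#' @export
soft_adjacency <- function(rho, beta = 6, signed = TRUE) {
  A <- if (signed) ((1 + rho) / 2)^beta else abs(rho)^beta
  diag(A) <- 0
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_u a_iu`, and `TOM_ii = 1`: the fraction of shared
#' network neighborhood between two nodes.
#'
#' @param A Symmetric adjacency with entries in \[0, 1\] and zero diagonal.
#' @return TOM matrix, symmetric with entries in \[0, 1\].
#' @export
topological_overlap <- function(A) {
  stopifnot(isSymmetric(unname(A)), all(A >= 0 & A <= 1),
            all(diag(A) == 0))
  k <- colSums(A)
  num <- A %*% A + A          # a_ii = 0 removes u = i, j from the sum
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect modules by hierarchical clustering of the TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a static height; clusters smaller than the minimum module size are
#' left unassigned (module 0), and modules are renumbered by decreasing size
#' (ties broken by first occurrence).
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param config A [network_config()].
#' @return Data frame `metabolite`, `module` (integer, 0 = unassigned).
#' @export
detect_modules <- function(tom, config = network_config()) {
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = config$cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= config$min_module_size]
  module <- integer(length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (m in seq_along(keep)) module[raw == keep[m]] <- m
  }
  data.frame(metabolite = colnames(tom), module = module,
             stringsAsFactors = FALSE)
}

#' Hub metabolite of each module
#'
#' The module member with the highest intramodular connectivity (sum of
#' within-module adjacency); ties break by metabolite name order.
#'
#' @param assignment Data frame from [detect_modules()].
#' @param A Adjacency matrix used for the network.
#' @return Data frame `module`, `hub`, `connectivity`.
#' @export
hub_metabolite <- function(assignment, A) {
  mods <- sort(unique(assignment$module[assignment$module > 0]))
  rows <- lapply(mods, function(m) {
    members <- sort(assignment$metabolite[assignment$module == m])
    k_in <- rowSums(A[members, members, drop = FALSE])
    i <- which.max(k_in)  # members sorted, so ties go to the first name
    data.frame(module = m, hub = members[i], connectivity = unname(k_in[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(module = integer(0), hub = character(0),
               connectivity = numeric(0))
}

#' Eigen-metabolite (PC1) module scores
#'
#' Standardizes each module's metabolites (zero mean, unit variance across
#' visits) and takes the first principal component of the module submatrix as
#' the per-visit module score, with the sign oriented so the score correlates
#' positively with the module's mean metabolite profile.
#'
#' @param log2_panel Numeric matrix, visits x metabolites (no missing values).
#' @param assignment Data frame from [detect_modules()].
#' @return List with `scores` (visits x modules matrix, columns
#'   `module_<id>`) and `var_explained` (PC1 variance fraction per module).
#' @export
module_scores <- function(log2_panel, assignment) {
  mods <- sort(unique(assignment$module[assignment$module > 0]))
  scores <- matrix(NA_real_, nrow(log2_panel), length(mods),
                   dimnames = list(rownames(log2_panel),
                                   paste0("module_", mods)))
  varexp <- setNames(numeric(length(mods)), paste0("module_", mods))
  for (i in seq_along(mods)) {
    members <- assignment$metabolite[assignment$module == mods[i]]
    if (length(members) < 2)
      stop("module ", mods[i], " has fewer than 2 members", call. = FALSE)
    X <- scale(log2_panel[, members, drop = FALSE])
    sv <- svd(X)
    pc1 <- sv$u[, 1] * sv$d[1]
    if (cor(pc1, rowMeans(X)) < 0) pc1 <- -pc1
    scores[, i] <- pc1
    varexp[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(scores = scores, var_explained = varexp)
}

#' Longitudinal group contrasts on module scores
#'
#' Fits the same mixed model as the per-metabolite screen with each module's
#' eigen-metabolite score as the response, and reports the pairwise
#' group-by-time contrasts of each declining group versus no decline.
#'
#' @param scores Matrix from [module_scores()] (`$scores`), rows = visit ids.
#' @param labels,dataset,covariates As in [screen_all()].
#' @param alpha Significance threshold for the reported flag (default 0.05).
#' @return Data frame, one row per module and contrast: `module`, `group`,
#'   `beta`, `se`, `p`, `significant`.
#' @export
module_group_lme <- function(scores, labels, dataset,
                             covariates = DEFAULT_COVARIATES, alpha = 0.05) {
  dataset <- anchor_time(dataset)
  frame <- build_screen_frame(dataset, labels)
  S <- scores[match(frame$visit_id, rownames(scores)), , drop = FALSE]
  rows <- list()
  for (j in seq_len(ncol(S))) {
    if (sd(S[, j], na.rm = TRUE) == 0)
      stop("degenerate fit: module score '", colnames(S)[j],
           "' is constant", call. = FALSE)
    fit <- fit_metabolite_lme(S[, j], frame, covariates = covariates)
    for (g in phenotype_levels()[-1]) {
      ct <- pairwise_longitudinal_contrast(fit, g)
      rows[[length(rows) + 1L]] <- data.frame(
        module = colnames(S)[j], group = g, beta = ct$beta, se = ct$se,
        p = ct$p, significant = !is.na(ct$p) && ct$p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
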