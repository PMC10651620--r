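# Competitive metabolite-class enrichment: for each class, a one-sided
# Wilcoxon rank-sum test asking whether the class's screening p-values rank
# lower (more significant) than those of all other metabolites.

#' Class enrichment of screening results
#'
#' For every metabolite class of size at least `min_size`, compares the
#' omnibus p-values of in-class metabolites against all remaining metabolites
#' with a one-sided Wilcoxon rank-sum test (alternative: in-class p-values
#' are smaller). The null distribution is exact for class sizes up to 10 when
#' the p-values are tie-free, and a normal approximation with tie correction
#' otherwise. Classes below `min_size` are reported but flagged not
#' estimable; a class containing every metabolite has no out-group and gets
#' p = 1 by convention.
#'
#' @param screen_table Data frame from [screen_all()] (needs `metabolite` and
#'   the `p_column`).
#' @param class_map Optional data frame `metabolite`, `class`; defaults to
#'   the `class` column of `screen_table`. Every screened metabolite must be
#'   mapped to exactly one class.
#' @param min_size Minimum class size to test (default 2).
#' @param p_column Which p-value column ranks the metabolites (default
#'   `"p_omnibus"`).
#' @return Data frame `class`, `size`, `statistic` (rank-sum W), `p`,
#'   `estimable`, ordered by p.
#' @export
enrich_classes <- function(screen_table, class_map = NULL, min_size = 2,
                           p_column = "p_omnibus") {
  if (is.null(class_map))
    class_map <- data.frame(metabolite = screen_table$metabolite,
                            class = screen_table$class,
                            stringsAsFactors = FALSE)
  idx <- match(screen_table$metabolite, class_map$metabolite)
  if (anyNA(idx) || anyNA(class_map$class[idx]))
    stop("metabolite without a class mapping: ",
         screen_table$metabolite[which(is.na(idx) |
                                         is.na(class_map$class[idx]))[1]],
         call. = FALSE)
  cls <- class_map$class[idx]
  p <- screen_table[[p_column]]
  keep <- !is.na(p)
  p <- p[keep]
  cls <- cls[keep]

  out <- lapply(unique(cls), function(cl) {
    p_in <- p[cls == cl]
    p_out <- p[cls != cl]
    size <- length(p_in)
    if (size < min_size)
      return(data.frame(class = cl, size = size, statistic = NA_real_,
                        p = NA_real_, estimable = FALSE))
    if (!length(p_out))  # degenerate: no out-group to compete against
      return(data.frame(class = cl, size = size, statistic = NA_real_,
                        p = 1, estimable = TRUE))
    exact <- size <= 10 && !anyDuplicated(p)
    wt <- suppressWarnings(
      wilcox.test(p_in, p_out, alternative = "less", exact = exact,
                  correct = !exact))
    data.frame(class = cl, size = size,
               statistic = unname(wt$statistic), p = wt$p.value,
               estimable = TRUE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}

#' Export significant metabolites for external pathway mapping
#'
#' Pathway enrichment against curated databases requires external identifier
#' mapping; this helper emits the significant metabolite names with empty ID
#' columns as a mapping template.
#'
#' @param screen_table Data frame from [screen_all()].
#' @param p_column,alpha Selection rule (default `p_dual < 0.05`, the
#'   dual-decline longitudinal contrast).
#' @return Data frame `metabolite`, `class`, `p`, `hmdb_id`, `kegg_id` (IDs
#'   blank, to be filled from an external source).
#' @export
export_significant <- function(screen_table, p_column = "p_dual",
                               alpha = 0.05) {
  sel <- !is.na(screen_table[[p_column]]) & screen_table[[p_column]] < alpha
  n <- sum(sel)
  data.frame(metabolite = screen_table$metabolite[sel],
             class = screen_table$class[sel],
             p = screen_table[[p_column]][sel],
             hmdb_id = rep("", n), kegg_id = rep("", n),
             stringsAsFactors = FALSE)
}
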