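`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded internals never perturb user-level randomness.
#' @noRd
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Deterministic per-stage child seed
#'
#' Fans a single pipeline seed out to stage-specific seeds so stages can be
#' rerun in isolation. Always below 2^31.
#' @noRd
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# comma for .csv, tab for anything else (.tsv/.txt)
delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

write_table_auto <- function(df, path) {
  write.table(df, path, sep = delim_for(path), quote = FALSE,
              row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# inverse-CDF truncated normal draw (deterministic given the RNG state)
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("column '", miss[1], "' missing from ", what, call. = FALSE)
  invisible(TRUE)
}
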