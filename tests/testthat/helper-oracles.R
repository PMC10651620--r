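# Independent brute-force oracles used across the suite. Each applies the
# defining formula directly, with no shared code with the implementation.

# step-up FDR by definition: q_(i) = min_{j >= i} m * p_(j) / j, capped at 1
bf_bh <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  n <- length(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[o[i]] <- min(1, min(m * ps[i:n] / (i:n)))
  }
  q
}

# topological overlap by triple loop
bf_tom <- function(A) {
  n <- nrow(A)
  tom <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(A[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
    tom[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(tom) <- dimnames(A)
  tom
}

# exhaustive four-group labeler
bf_label <- function(mem_slope, gait_slope, mem_cut, gait_cut) {
  m <- mem_slope <= mem_cut
  g <- gait_slope <= gait_cut
  if (m && g) return("dual_decline")
  if (m && !g) return("memory_decline_only")
  if (!m && g) return("gait_decline_only")
  "no_decline"
}

# least-squares slope by iterative grid refinement of the SSE over the slope
# (intercept profiled out at each candidate), to ~1e-8
bf_slope_grid <- function(t, y, lo = -50, hi = 50) {
  for (it in 1:14) {
    b <- seq(lo, hi, length.out = 401)
    sse <- vapply(b, function(bi) {
      a <- mean(y) - bi * mean(t)
      sum((y - a - bi * t)^2)
    }, 0)
    i <- which.min(sse)
    lo <- b[max(1, i - 1)]
    hi <- b[min(length(b), i + 1)]
  }
  (lo + hi) / 2
}

# 33 1/3 percentile with linear interpolation between order statistics
# (h = (n - 1) p + 1 on the sorted sample)
bf_tertile <- function(x) {
  s <- sort(x)
  h <- (length(s) - 1) / 3 + 1
  f <- floor(h)
  s[f] + (h - f) * (s[min(length(s), f + 1)] - s[f])
}

# dominant right singular direction by power iteration on the covariance
bf_pc1_scores <- function(X, iters = 500) {
  C <- crossprod(X) / (nrow(X) - 1)
  v <- rep(1, ncol(X))
  for (i in seq_len(iters)) {
    v <- C %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.numeric(X %*% v)
}

# one-sample Kolmogorov-Smirnov distance against a cdf
ks_distance <- function(x, cdf) {
  n <- length(x)
  u <- sort(cdf(x))
  max(pmax(abs(seq_len(n) / n - u), abs(u - (seq_len(n) - 1) / n)))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
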