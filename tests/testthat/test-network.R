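test_that("Spearman matrix handles monotone relations and matches rank-then-Pearson", {
  set.seed(21)
  x <- runif(30)
  X <- cbind(a = x, b = 2 * x, c = -x^3, d = rnorm(30))
  rho <- spearman_matrix(X)
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  Y <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("m", 1:4)))
  expect_equal(unname(spearman_matrix(Y)),
               unname(cor(apply(Y, 2, rank))), tolerance = 1e-12)
  X[, "d"] <- 1
  expect_error(spearman_matrix(X), "'d'")
})

test_that("signed soft adjacency follows ((1+rho)/2)^beta", {
  rho <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(soft_adjacency(rho, 6)[1, 2], 1)
  expect_equal(soft_adjacency(matrix(c(1, -1, -1, 1), 2), 6)[1, 2], 0)
  expect_equal(soft_adjacency(matrix(c(1, 0, 0, 1), 2), 6)[1, 2], 0.015625)
  expect_equal(soft_adjacency(matrix(c(1, -0.5, -0.5, 1), 2), 2,
                              signed = FALSE)[1, 2], 0.25)
  expect_equal(diag(soft_adjacency(rho, 6)), c(0, 0))
})

test_that("topological overlap matches the triple-loop oracle and its edge cases", {
  A2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(topological_overlap(A2)[1, 2], 1)
  expect_equal(topological_overlap(matrix(0, 3, 3))[1, 2], 0)
  set.seed(33)
  for (r in 1:10) {
    n <- sample(3:12, 1)
    A <- matrix(runif(n * n), n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    tom <- topological_overlap(A)
    expect_equal(tom, bf_tom(A), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("module detection finds planted blocks and leaves noise unassigned", {
  bp <- block_panel(seed = 1)
  tom <- topological_overlap(soft_adjacency(spearman_matrix(bp$X)))
  mod <- detect_modules(tom)
  expect_gte(adjusted_rand(mod$module, bp$truth), 0.9)
  expect_equal(sort(unique(mod$module)), 1:3)
  # modules numbered by decreasing size
  expect_equal(unname(table(mod$module)[c("1", "2", "3")]),
               as.array(c(20L, 15L, 10L)), ignore_attr = TRUE)

  # pure noise: nothing clusters
  set.seed(2)
  N <- matrix(rnorm(100 * 30), 100, 30,
              dimnames = list(NULL, sprintf("n%02d", 1:30)))
  tomN <- topological_overlap(soft_adjacency(spearman_matrix(N)))
  expect_true(all(detect_modules(tomN)$module == 0))

  # one perfect block clusters completely
  x <- rnorm(50)
  P <- sapply(1:6, function(j) j * x + j)
  colnames(P) <- paste0("p", 1:6)
  tomP <- topological_overlap(soft_adjacency(spearman_matrix(P)))
  expect_true(all(detect_modules(tomP)$module == 1))
})

test_that("module labels are invariant to metabolite input order", {
  bp <- block_panel(seed = 4)
  tom1 <- topological_overlap(soft_adjacency(spearman_matrix(bp$X)))
  m1 <- detect_modules(tom1)
  set.seed(5)
  perm <- sample(ncol(bp$X))
  tom2 <- topological_overlap(soft_adjacency(spearman_matrix(bp$X[, perm])))
  m2 <- detect_modules(tom2)
  i <- match(m1$metabolite, m2$metabolite)
  expect_equal(adjusted_rand(m1$module, m2$module[i]), 1)
})

test_that("hub metabolites have maximal intramodular connectivity, ties by name", {
  # star: center strongly tied to all, leaves weakly tied to each other
  n <- 6
  A <- matrix(0.1, n, n)
  A[1, ] <- A[, 1] <- 0.9
  diag(A) <- 0
  dimnames(A) <- list(paste0("m", 1:n), paste0("m", 1:n))
  asg <- data.frame(metabolite = rownames(A), module = 1L)
  expect_equal(hub_metabolite(asg, A)$hub, "m1")

  A2 <- matrix(c(0, 0.5, 0.5, 0), 2,
               dimnames = list(c("zeta", "alpha"), c("zeta", "alpha")))
  asg2 <- data.frame(metabolite = c("zeta", "alpha"), module = 1L)
  expect_equal(hub_metabolite(asg2, A2)$hub, "alpha")  # lexicographic tie

  # brute-force check on every module of a random assignment
  set.seed(6)
  B <- matrix(runif(100), 10)
  B <- (B + t(B)) / 2
  diag(B) <- 0
  dimnames(B) <- list(paste0("x", 1:10), paste0("x", 1:10))
  asg3 <- data.frame(metabolite = rownames(B),
                     module = rep(1:2, each = 5))
  hubs <- hub_metabolite(asg3, B)
  for (m in 1:2) {
    members <- asg3$metabolite[asg3$module == m]
    ks <- rowSums(B[members, members])
    expect_equal(hubs$hub[hubs$module == m],
                 members[which.max(ks)])
  }
})

test_that("module PC1 scores match power iteration, orientation and variance contracts", {
  set.seed(7)
  x <- rnorm(30)
  X <- cbind(a = x, b = x)  # identical columns after standardization
  asg <- data.frame(metabolite = c("a", "b"), module = 1L)
  ms <- module_scores(X, asg)
  expect_equal(unname(ms$var_explained), 1)
  expect_equal(abs(cor(ms$scores[, 1], x)), 1)

  Y <- matrix(rnorm(150), 30, 5, dimnames = list(NULL, paste0("m", 1:5)))
  asgY <- data.frame(metabolite = paste0("m", 1:5), module = 1L)
  msY <- module_scores(Y, asgY)
  oracle <- bf_pc1_scores(scale(Y))
  agree <- cor(msY$scores[, 1], oracle)
  expect_equal(abs(agree), 1, tolerance = 1e-8)
  # orientation: positively correlated with the module mean profile
  expect_gt(cor(msY$scores[, 1], rowMeans(scale(Y))), 0)
})

test_that("module score group models run end to end and reject constant scores", {
  sim <- simulate_cohort(sim_params("smoke", seed = 91, n_subjects = 80L,
                                    dementia_frac = 0))
  processed <- log2_matrix(filter_by_lod(sim$dataset$panel)$panel)
  labels <- truth_labels(sim)
  scores <- matrix(rnorm(nrow(processed$log2)),
                   dimnames = list(rownames(processed$log2), "module_1"))
  res <- module_group_lme(scores, labels, sim$dataset)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p >= 0 & res$p <= 1))
  const <- matrix(1, nrow(processed$log2), 1,
                  dimnames = list(rownames(processed$log2), "module_1"))
  expect_error(module_group_lme(const, labels, sim$dataset), "degenerate")
})
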