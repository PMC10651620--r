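test_that("per-subject OLS slopes match exact lines and the grid-refined SSE minimizer", {
  d <- slopes_from_series(list(
    s1 = list(t = c(0, 1, 2), mem = c(10, 9, 8)),
    s2 = list(t = c(0, 2, 4), gait = c(1.2, 1.2, 1.2)),
    s3 = list(t = 0:3, gait = c(1.00, 1.10, 0.95, 1.15))))
  sl <- estimate_annual_slopes(d)
  expect_equal(sl$memory_slope[sl$subject_id == "s1"], -1.0)
  expect_equal(sl$gait_slope[sl$subject_id == "s2"], 0.0)
  oracle <- bf_slope_grid(0:3, c(1.00, 1.10, 0.95, 1.15))
  expect_equal(sl$gait_slope[sl$subject_id == "s3"], oracle,
               tolerance = 1e-6)

  set.seed(401)
  for (r in 1:20) {
    n <- sample(3:8, 1)
    t <- sort(runif(n, 0, 10))
    y <- 40 + rnorm(n, 0, 5)
    d <- slopes_from_series(setNames(list(list(t = t, mem = pmin(80, pmax(0, y)))), "x"))
    sl <- estimate_annual_slopes(d)
    expect_equal(sl$memory_slope, bf_slope_grid(t, d$visits$memory_score),
                 tolerance = 1e-6)
  }
})

test_that("visits at and after dementia onset are excluded from slope estimation", {
  d <- slopes_from_series(list(
    s1 = list(t = c(0, 1, 2, 3), mem = c(50, 49, 10, 5))))
  d$subjects$dementia_onset_time <- 2
  sl <- estimate_annual_slopes(d)
  expect_equal(sl$memory_slope, -1.0)  # only t = 0, 1 used
  expect_equal(sl$n_points_memory, 2L)
  sl2 <- estimate_annual_slopes(d, exclude_post_dementia = FALSE)
  expect_lt(sl2$memory_slope, -10)
})

test_that("subjects with too few eligible points are omitted and logged", {
  d <- slopes_from_series(list(
    s1 = list(t = c(0, 1, 2), mem = c(50, 49, 48)),
    s2 = list(t = c(0, 1), mem = c(50, NA))))
  d$visits$memory_score[d$visits$visit_id == "s2_v2"] <- NA
  sl <- estimate_annual_slopes(d)
  expect_false("s2" %in% sl$subject_id)
  om <- attr(sl, "omitted")
  expect_true("s2" %in% om$subject_id)
})

test_that("tertile cut-points follow the interpolated 33 1/3 percentile definition", {
  x <- c(-3, -2, -1, 0, 1, 2, 3, 4, 5)
  sl <- data.frame(subject_id = paste0("s", 1:9),
                   memory_slope = x, gait_slope = x / 10)
  cuts <- tertile_cutpoints(sl)
  expect_equal(cuts$memory_cut, bf_tertile(x))
  expect_equal(cuts$memory_cut, -1 / 3, tolerance = 1e-12)
  expect_equal(cuts$gait_cut, bf_tertile(x / 10))

  sl2 <- data.frame(subject_id = paste0("s", 1:5),
                    memory_slope = rep(2.5, 5), gait_slope = rep(-0.1, 5))
  expect_equal(tertile_cutpoints(sl2)$memory_cut, 2.5)
  expect_error(tertile_cutpoints(sl2[1:2, ]), "at least 3 subjects")
})

test_that("classification applies the published cut-points correctly, ties declining", {
  cuts <- structure(list(memory_cut = -0.67, gait_cut = -0.022),
                    class = "cutpoints")
  sl <- data.frame(
    subject_id = c("a", "b", "c", "d"),
    memory_slope = c(-0.8, -0.8, -0.67, 0.1),
    gait_slope = c(-0.01, -0.03, -0.022, -0.5))
  lab <- classify_phenotypes(sl, cuts)
  expect_equal(as.character(lab$label),
               c("memory_decline_only", "dual_decline", "dual_decline",
                 "gait_decline_only"))
})

test_that("labels agree with the brute-force labeler and partition the sample", {
  set.seed(777)
  for (r in 1:200) {
    n <- sample(3:30, 1)
    sl <- data.frame(subject_id = paste0("s", 1:n),
                     memory_slope = rnorm(n), gait_slope = rnorm(n, 0, 0.05))
    cuts <- if (r %% 2) tertile_cutpoints(sl)
            else structure(list(memory_cut = rnorm(1),
                                gait_cut = rnorm(1, 0, 0.05)),
                           class = "cutpoints")
    lab <- classify_phenotypes(sl, cuts)
    expect_equal(nrow(lab), n)  # partition: every subject exactly one label
    bf <- mapply(bf_label, sl$memory_slope, sl$gait_slope,
                 cuts$memory_cut, cuts$gait_cut)
    expect_identical(as.character(lab$label), unname(bf))
    if (r %% 2) {
      n_mem <- sum(lab$label %in% c("memory_decline_only", "dual_decline"))
      expect_gte(n_mem, floor(n / 3))
      expect_lte(n_mem, ceiling(n / 3) +
                   sum(sl$memory_slope == cuts$memory_cut))
    }
  }
})

test_that("noise-free planted groups are recovered perfectly with midpoint cuts", {
  p <- noise_free_params(seed = 9, n_subjects = 120L)
  sim <- simulate_cohort(p)
  sl <- estimate_annual_slopes(sim$dataset)
  lab <- classify_phenotypes(sl, midpoint_cuts(p))
  tr <- sim$truth$subjects
  expect_equal(as.character(lab$label),
               tr$group[match(lab$subject_id, tr$subject_id)])
})

test_that("subjects with missing slopes are omitted from classification with a log", {
  sl <- data.frame(subject_id = c("a", "b"),
                   memory_slope = c(-1, NA), gait_slope = c(-0.1, -0.2))
  lab <- classify_phenotypes(
    sl, structure(list(memory_cut = 0, gait_cut = 0), class = "cutpoints"))
  expect_equal(lab$subject_id, "a")
  expect_equal(attr(lab, "omitted")$subject_id, "b")
})
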