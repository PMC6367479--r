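test_that("a noiseless line is recovered exactly", {
  t <- seq(-60, 60, by = 5)
  f <- fit_linear_mae(t, 0.5 * t + 10)
  expect_equal(f$g, 0.5, tolerance = 1e-6)
  expect_equal(f$b, 10, tolerance = 1e-6)
  expect_equal(f$r2, 1)
  expect_equal(f$mae, 0, tolerance = 1e-6)
  ident <- fit_linear_mae(t, t)
  expect_equal(ident$g, 1, tolerance = 1e-9)
  expect_equal(ident$b, 0, tolerance = 1e-9)
})

test_that("constant responses fit a flat line at the response level", {
  t <- seq(-60, 85, by = 2.5)
  f <- fit_linear_mae(t, rep(30, length(t)))
  expect_equal(f$g, 0, tolerance = 1e-6)
  expect_equal(f$b, 30, tolerance = 1e-6)
})

test_that("degenerate targets flag the fit and return the median response", {
  f <- fit_linear_mae(rep(5, 10), c(1:9, 100))
  expect_true(f$degenerate)
  expect_true(is.na(f$g))
  expect_equal(f$b, 5.5)
  expect_error(fit_linear_mae(1:2, 1:2), "at least 3")
})

test_that("simplex fit matches the brute-force oracle on random small datasets", {
  set.seed(123)
  for (k in 1:100) {
    t <- runif(20, -60, 85)
    g0 <- runif(1, -1.5, 1.5)
    b0 <- runif(1, -45, 45)
    y <- g0 * t + b0 + rnorm(20, 0, 8)
    f <- fit_linear_mae(t, y)
    o <- oracle_mae(t, y)
    expect_lte(abs(f$g - o["g"]), 0.001 + 1e-9)
    # the fitted objective is never worse than the oracle's best grid point
    expect_lte(f$mae, o["obj"] + 1e-9)
  }
})

test_that("MAE fitting recovers parameters under Laplace noise within 2 SE", {
  # MAE minimization is maximum likelihood under Laplace errors
  set.seed(99)
  g0 <- 0.7; b0 <- 12; scale <- 6; n <- 48
  reps <- 200
  fits <- t(replicate(reps, {
    t <- runif(n, -60, 85)
    y <- g0 * t + b0 + scale * (rexp(n) - rexp(n)) / sqrt(2)
    f <- fit_linear_mae(t, y)
    c(f$g, f$b)
  }))
  se_g <- sd(fits[, 1]) / sqrt(reps)
  se_b <- sd(fits[, 2]) / sqrt(reps)
  expect_lt(abs(mean(fits[, 1]) - g0), 2 * se_g + 0.01)
  expect_lt(abs(mean(fits[, 2]) - b0), 2 * se_b + 0.5)
  # single-dataset recovery within 2 SE of the sampling spread
  t <- runif(n, -60, 85)
  y <- g0 * t + b0 + scale * (rexp(n) - rexp(n)) / sqrt(2)
  f <- fit_linear_mae(t, y)
  expect_lt(abs(f$g - g0), 2 * sd(fits[, 1]))
  expect_lt(abs(f$b - b0), 2 * sd(fits[, 2]))
})

test_that("scaling both axes scales the bias and preserves the gain", {
  set.seed(5)
  t <- runif(30, -60, 85)
  y <- 0.6 * t + 8 + rnorm(30, 0, 5)
  f1 <- fit_linear_mae(t, y)
  f2 <- fit_linear_mae(3 * t, 3 * y)
  expect_equal(f2$g, f1$g, tolerance = 1e-4)
  expect_equal(f2$b, 3 * f1$b, tolerance = 1e-3)
})

test_that("r-squared is the square of Pearson r", {
  set.seed(6)
  t <- runif(40, -60, 85)
  y <- 0.4 * t + rnorm(40, 0, 10)
  f <- fit_linear_mae(t, y)
  expect_equal(f$r2, f$r^2, tolerance = 1e-12)
  expect_equal(f$r, cor(t, y))
})

test_that("an identity trial table yields 25 perfect condition fits", {
  d <- build_design(targets = 10, seed = 13)
  tr <- d$trials
  tr$elevation_r_deg <- tr$elevation_t_deg
  tr$azimuth_r_deg <- tr$azimuth_t_deg
  s <- summarize_conditions(tr)
  expect_equal(nrow(s$conditions), 25)
  expect_equal(s$conditions$g, rep(1, 25), tolerance = 1e-6)
  expect_equal(s$conditions$b, rep(0, 25), tolerance = 1e-4)
  expect_equal(s$conditions$r2, rep(1, 25), tolerance = 1e-12)
  # profiles: 9 contrast levels, 5 diagonal levels
  expect_equal(nrow(s$by_contrast), 9)
  expect_equal(nrow(s$by_level), 5)
  expect_equal(s$by_contrast$g, rep(1, 9), tolerance = 1e-6)
  # pooled profiles agree on identity data
  sp <- summarize_conditions(tr, pool = TRUE)
  expect_equal(sp$by_contrast$g, rep(1, 9), tolerance = 1e-6)
})

test_that("sparse conditions are flagged and excluded from profiles", {
  d <- build_design(targets = 10, seed = 14)
  tr <- d$trials
  tr$elevation_r_deg <- tr$elevation_t_deg
  tr <- tr[!(tr$nri_db == 29 & tr$ori_db == 29) | seq_len(nrow(tr)) %in%
             which(tr$nri_db == 29 & tr$ori_db == 29)[1:2], ]
  s <- summarize_conditions(tr)
  flagged <- s$conditions[s$conditions$nri_db == 29 & s$conditions$ori_db == 29, ]
  expect_true(flagged$flagged)
  expect_equal(nrow(s$by_level), 4)
})

test_that("double-pole coordinates respect |azimuth| + |elevation| <= 90", {
  expect_equal(unlist(double_pole_from_cartesian(c(1, 0, 0))), c(0, 0),
               ignore_attr = TRUE)
  expect_equal(double_pole_from_cartesian(c(0, 0, 1))$elevation_deg, 90)
  set.seed(17)
  n <- 10000
  v <- cbind(abs(rnorm(n)), rnorm(n), rnorm(n))
  dp <- double_pole_from_cartesian(v)
  expect_true(all(abs(dp$azimuth_deg) + abs(dp$elevation_deg) <= 90 + 1e-9))
  expect_error(double_pole_from_cartesian(c(0, 0, 0)), "zero")
  expect_error(double_pole_from_cartesian(c(-1, 0, 0)), "frontal")
})

test_that("rear unfolding is the stated reflection and an involution", {
  expect_equal(rear_unfold(60), 120)
  expect_equal(rear_unfold(90), 90)
  for (e in seq(-90, 90, by = 15)) expect_equal(rear_unfold(rear_unfold(e)), e)
  expect_error(rear_unfold(-120), "range")
})

test_that("two-cluster gap detects separated clusters and ignores unimodal data", {
  bim <- c(rnorm(30, -50, 3), rnorm(20, 60, 3))
  expect_true(two_cluster_gap(bim)$bimodal)
  uni <- rnorm(50, 10, 5)
  expect_false(two_cluster_gap(uni)$bimodal)
  # a lone outlier is not a cluster
  out <- c(rnorm(49, 0, 3), 80)
  expect_false(two_cluster_gap(out)$bimodal)
})
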