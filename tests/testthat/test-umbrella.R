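test_that("effect grids meet their three defining characteristics", {
  expect_equal(effect_grid(2, 0, 0, 0.1), c(0.1, 0.1))
  expect_equal(effect_grid(2, 0, 0.8, 0.1), c(0.02, 0.18))
  expect_equal(effect_grid(4, 1, 0, 0.1), rep(0, 4))
  expect_equal(effect_grid(2, 1 / 2, 0, 0.1), c(0, 0.1))

  th <- effect_grid(4, 1 / 4, 0.4, 0.1)
  expect_equal(sum(th == 0), 1)
  pos <- th[th > 0]
  expect_equal(mean(pos), 0.1)
  expect_equal((max(pos) - min(pos)) / (max(pos) + min(pos)), 0.4)
  expect_equal(diff(pos), rep(diff(pos)[1], 2))   # equidistant

  expect_error(effect_grid(4, 0.3, 0, 0.1), "integer")
  expect_error(effect_grid(2, 1 / 2, 0.4, 0.1), "tau = 0")
  expect_error(effect_grid(4, 0, 1, 0.1), "tau < 1")
})

test_that("subset statistics equal the least-squares reference fit", {
  d <- umbrella_design(l = 3, N = 60)
  s <- population_structure(c("1" = 1 / 3, "2" = 1 / 3, "3" = 1 / 3))
  dat <- simulate_trial(s, "umbrella", effects = c(0, 0.2, 0.4), sigma = 1,
                        N = 60, seed = 5)
  got <- fit_subset_statistics(dat, d)
  ref <- lm_subset_statistics(dat, d)
  expect_equal(got$statistics, ref, tolerance = 1e-10)
  expect_equal(got$df, 54)
})

test_that("with one stratum the subset statistic is the pooled two-sample t", {
  d <- umbrella_design(l = 1, N = 40)
  s <- population_structure(c("1" = 1))
  dat <- simulate_trial(s, "umbrella", effects = 0.3, sigma = 1, N = 40, seed = 9)
  got <- fit_subset_statistics(dat, d)$statistics[["1"]]
  tt <- stats::t.test(outcome ~ arm == "C", data = dat, var.equal = TRUE)
  expect_equal(got, unname(tt$statistic), tolerance = 1e-10)
})

test_that("degenerate data with zero residual variance is rejected", {
  d <- umbrella_design(l = 2, N = 8)
  dat <- data.frame(stratum = rep(c("1", "2"), each = 4),
                    arm = rep(c("T1", "C", "T2", "C"), each = 2),
                    outcome = 1)
  expect_error(fit_subset_statistics(dat, d), "zero residual variance")
})

test_that("null subset statistics are marginally t with N - 2l df", {
  d <- umbrella_design(l = 2, N = 40)
  s <- population_structure(c("1" = 0.5, "2" = 0.5))
  n_reps <- 2000
  set.seed(13)
  TS <- t(vapply(seq_len(n_reps), function(r) {
    dat <- simulate_trial(s, "umbrella", effects = c(0, 0), sigma = 1, N = 40)
    fit_subset_statistics(dat, d)$statistics
  }, numeric(3)))
  for (j in 1:3) {
    ks <- stats::ks.test(TS[, j], stats::pt, df = 36)
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("subset selection takes the argmax above the threshold, ties to the
           smallest set", {
  stats1 <- c("1" = 1.0, "2" = 0.5, "1+2" = 1.5)
  expect_identical(select_subset(stats1, 2)$selected, integer(0))
  expect_true(is.na(select_subset(stats1, 2)$label))

  stats2 <- c("1" = 3.0, "2" = 0.5, "1+2" = 2.5)
  expect_identical(select_subset(stats2, 2.2)$selected, 1L)

  tied <- c("1" = 3.0, "2" = 0.5, "1+2" = 3.0)
  expect_identical(select_subset(tied, 2.2)$label, "1")
  tied2 <- c("1+2" = 3.0, "2" = 3.0, "1" = 1.0)
  expect_identical(select_subset(tied2, 2.2)$label, "2")
})

test_that("umbrella critical values: l = 1 marginal quantile, PWER below FWER", {
  d1 <- umbrella_design(l = 1, N = 100)
  cv1 <- umbrella_critical_values(d1)
  expect_equal(cv1$c_pwer, stats::qt(0.975, df = 98), tolerance = 1e-5)
  expect_equal(cv1$c_fwer, stats::qt(0.975, df = 98), tolerance = 1e-5)

  d2 <- umbrella_design(l = 2, N = 1056)
  cv2 <- umbrella_critical_values(d2)
  expect_lt(cv2$c_pwer, cv2$c_fwer)
  expect_gt(cv2$c_pwer, stats::qt(0.975, df = 1052))
})

test_that("the calibrated PWER threshold attains the level under resampling", {
  d <- umbrella_design(l = 2, N = 1056)
  cv <- umbrella_critical_values(d)
  s <- population_structure(c("1" = 0.5, "2" = 0.5))
  mc <- mc_pwer_oracle(s, cv$model, cv$c_pwer, n_draws = 2e5, seed = 8)
  expect_lt(abs(mc$estimate - 0.025), 3 * mc$se)
})

test_that("the performance study orders PWER above FWER and keeps the null
           false-selection near its theory value", {
  d <- umbrella_design(l = 2, N = 1056)
  res <- run_performance_study(d, data.frame(q = c(0, 1), tau = c(0, 0)),
                               n_reps = 2000, seed = 3)
  expect_equal(nrow(res), 4)
  expect_true(all(res$correct + res$false <= 100 + 1e-9))
  expect_true(all(res$power >= 0 & res$power <= 100))

  g <- function(q, meth, col) res[res$q == q & res$method == meth, col]
  # whenever FWER selects, PWER selects the same set: all measures ordered
  expect_gte(g(0, "PWER", "power"), g(0, "FWER", "power"))
  expect_gte(g(0, "PWER", "rae"), g(0, "FWER", "rae"))
  # global null: false proportion for FWER-control is the one-sided FWER
  se3 <- 3 * 100 * sqrt(0.025 * 0.975 / 2000)
  expect_lt(abs(g(1, "FWER", "false") - 2.5), se3)
  # for PWER-control it exceeds alpha but stays below the strata bound
  expect_gt(g(1, "PWER", "false"), g(1, "FWER", "false") - se3)
  expect_lt(g(1, "PWER", "false"), 7)
  # no positive effects: power and RAE are zero by definition
  expect_equal(g(1, "PWER", "power"), 0)
  expect_equal(g(1, "PWER", "rae"), 0)
})

test_that("simulate method reproduces the design's layout", {
  d <- umbrella_design(l = 2, N = 48, effects = c(0.1, 0.2))
  dat <- stats::simulate(d, nsim = 1, seed = 4)
  expect_equal(nrow(dat), 48)
  expect_equal(sort(unique(dat$arm)), c("C", "T1", "T2"))
  counts <- table(dat$stratum, dat$arm == "C")
  expect_true(all(abs(counts[, "TRUE"] - counts[, "FALSE"]) <= 1))
})
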