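test_that("joint null models validate their correlation input", {
  m <- joint_null_model(0.5)
  expect_equal(m$k, 2)
  expect_equal(m$correlation[1, 2], 0.5)
  expect_identical(m$affects, list(1L, 2L))

  expect_error(joint_null_model(matrix(c(1, .2, .4, 1), 2)), "symmetric")
  expect_error(joint_null_model(matrix(c(2, 0, 0, 2), 2)), "unit diagonal")
  bad <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3)
  expect_error(joint_null_model(bad), "positive semi-definite")
  expect_error(joint_null_model(diag(2), family = "student_t"), "df")
})

test_that("two-population correlation formulas match their closed forms", {
  expect_equal(corr_two_pop_unequal_treatments(0), 0)
  expect_equal(corr_two_pop_unequal_treatments(0.2), 3 / 14)
  expect_equal(corr_two_pop_unequal_treatments(1), 0.5)
  expect_equal(corr_two_pop_equal_treatments(0), 0)
  expect_equal(corr_two_pop_equal_treatments(0.2), 1 / 3)
  expect_equal(corr_two_pop_equal_treatments(1), 1)
  # sharing treatment and control correlates more than sharing control only
  grid <- seq(0, 1, by = 0.05)
  expect_true(all(corr_two_pop_equal_treatments(grid) >=
                    corr_two_pop_unequal_treatments(grid)))
})

test_that("simulated shared-control trials reproduce the correlation formulas", {
  # the subject-level simulator is the independent oracle for the closed forms
  s <- two_pop_structure(0.2)
  n_reps <- 3000
  for (scen in c("unequal_treatments", "equal_treatments")) {
    set.seed(202)
    Z <- t(vapply(seq_len(n_reps), function(r) {
      dat <- simulate_trial(s, scen, effects = c(0, 0), sigma = 1, N = 180)
      fit_two_pop_statistics(dat, s, scen, sigma = 1)
    }, numeric(2)))
    target <- if (scen == "unequal_treatments") 3 / 14 else 1 / 3
    r_hat <- stats::cor(Z[, 1], Z[, 2])
    se <- (1 - target^2) / sqrt(n_reps)
    expect_lt(abs(r_hat - target), 3 * se)
    # marginals are standard normal: variance near 1
    expect_lt(abs(stats::sd(Z[, 1]) - 1), 0.05)
  }
})

test_that("nested-chain correlations are sqrt(pi_j / pi_i)", {
  s <- population_structure(c("1" = 0.75, "1+2" = 0.24, "1+2+3" = 0.01))
  R <- corr_nested_single_treatment(s)
  expect_equal(R[1, 2], 0.5)
  expect_equal(R[1, 3], 0.1)
  expect_equal(R[2, 3], 0.2)

  expect_equal(corr_nested_single_treatment(population_structure(c("1" = 1))),
               matrix(1, 1, 1))
  s2 <- population_structure(c("1" = 0.5, "1+2" = 0.5))
  expect_equal(corr_nested_single_treatment(s2)[1, 2], sqrt(0.5))
  expect_error(corr_nested_single_treatment(two_pop_structure(0.2)),
               "nested chain")
})

test_that("nested correlation matches pooled z-statistics by simulation", {
  # two nested populations, one treatment, balanced arms matching prevalences:
  # Z_2 uses the inner half of the sample that Z_1 pools over
  n_reps <- 4000
  n_inner <- 50   # per arm; outer stratum adds another 50 per arm
  set.seed(77)
  z1 <- numeric(n_reps); z2 <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    tin <- stats::rnorm(n_inner); cin <- stats::rnorm(n_inner)
    tout <- stats::rnorm(n_inner); cout <- stats::rnorm(n_inner)
    z2[r] <- (mean(tin) - mean(cin)) / sqrt(2 / n_inner)
    z1[r] <- (mean(c(tin, tout)) - mean(c(cin, cout))) / sqrt(2 / (2 * n_inner))
  }
  target <- sqrt(0.5)
  expect_lt(abs(stats::cor(z1, z2) - target), 3 * (1 - target^2) / sqrt(n_reps))
})

test_that("joint_tail matches marginals, the worked example, and its bounds", {
  m1 <- joint_null_model(matrix(1, 1, 1), labels = "1")
  expect_equal(joint_tail(m1, 1, stats::qnorm(0.975)), 0.025, tolerance = 1e-9)
  expect_equal(joint_tail(m1, 1, Inf), 0)

  R <- matrix(c(1, .5, .1, .5, 1, .2, .1, .2, 1), 3)
  m3 <- joint_null_model(R)
  expect_lt(abs(joint_tail(m3, 1:3, 2.037) - 0.0572), 5e-4)

  # monotone in c, between the max-marginal and Bonferroni bounds
  grid <- seq(1, 3, by = 0.25)
  tails <- vapply(grid, function(c) joint_tail(m3, 1:3, c), numeric(1))
  expect_true(all(diff(tails) < 0))
  marg <- stats::pnorm(grid, lower.tail = FALSE)
  expect_true(all(tails >= marg - 1e-10))
  expect_true(all(tails <= 3 * marg + 1e-10))
})

test_that("student-t joint tails converge to normal as df grows", {
  R <- matrix(c(1, .3, .3, 1), 2)
  mt <- joint_null_model(R, family = "student_t", df = 1e6)
  mn <- joint_null_model(R)
  for (c in c(1.5, 2, 2.5))
    expect_lt(abs(joint_tail(mt, 1:2, c) - joint_tail(mn, 1:2, c)), 1e-6)
})

test_that("umbrella null models have the stated size, df and correlations", {
  d <- umbrella_design(l = 2, N = 1056)
  m <- umbrella_null_model(d)
  expect_equal(m$k, 3)
  expect_equal(m$df, 1052)
  expect_identical(m$labels, c("1", "2", "1+2"))
  expect_equal(m$correlation["1", "2"], 0, tolerance = 1e-12)
  expect_equal(m$correlation["1", "1+2"], sqrt(0.5), tolerance = 1e-12)

  d1 <- umbrella_design(l = 1, N = 100)
  expect_equal(unname(umbrella_null_model(d1)$correlation), matrix(1, 1, 1))

  expect_error(umbrella_design(l = 2, N = 4), "N > 2")
  expect_error(umbrella_design(l = 13, N = 1e4), "l <= 12")
})

test_that("umbrella model correlations match simulated least-squares fits", {
  d <- umbrella_design(l = 2, N = 48)
  m <- umbrella_null_model(d)
  s <- population_structure(c("1" = 0.5, "2" = 0.5))
  n_reps <- 2500
  set.seed(99)
  TS <- t(vapply(seq_len(n_reps), function(r) {
    dat <- simulate_trial(s, "umbrella", effects = c(0, 0), sigma = 1, N = 48)
    fit_subset_statistics(dat, d)$statistics
  }, numeric(3)))
  emp <- stats::cor(TS)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(emp[i, j] - m$correlation[i, j]),
              3 * (1 - m$correlation[i, j]^2) / sqrt(n_reps) + 0.01)
})
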