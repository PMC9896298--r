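alpha <- 0.025
s22 <- two_pop_structure(0.2)
m22 <- two_pop_model(0.2, "unequal_treatments")
nested_s <- population_structure(c("1" = 0.75, "1+2" = 0.24, "1+2+3" = 0.01))
nested_m <- nested_model(nested_s)

test_that("pwer reduces to the marginal tail for a single population", {
  s <- population_structure(c("1" = 1))
  m <- joint_null_model(matrix(1, 1, 1), labels = "1")
  expect_equal(pwer(s, m, stats::qnorm(0.975)), 0.025, tolerance = 1e-9)
  expect_equal(pwer_critical_value(s, m, alpha)$c_star, stats::qnorm(0.975),
               tolerance = 1e-7)
})

test_that("the shared-control example calibrates near the printed value", {
  expect_lt(abs(pwer(s22, m22, 2.03) - alpha), 5e-4)
  cv <- pwer_critical_value(s22, m22, alpha)
  expect_lt(abs(cv$c_star - 2.03), 0.01)
  expect_lte(cv$achieved, alpha + 1e-8)
  expect_gte(cv$c_star, stats::qnorm(1 - alpha))
})

test_that("analytic pwer agrees with brute-force Monte-Carlo rejection counting", {
  set.seed(31)
  for (rep in 1:3) {
    m_pop <- sample(2:4, 1)
    s <- random_structure(m_pop)
    model <- joint_null_model(random_corr(m_pop),
                              labels = as.character(seq_len(m_pop)))
    c <- stats::runif(1, 1.6, 2.4)
    mc <- mc_pwer_oracle(s, model, c, n_draws = 2e5, seed = 1000 + rep)
    expect_lt(abs(pwer(s, model, c) - mc$estimate), 3 * mc$se)
  }
})

test_that("the independent-samples critical value matches the closed form", {
  s <- two_pop_structure(0.4)
  m <- two_pop_model(0.4, "independent")
  expect_equal(pwer_critical_value(s, m, alpha, tol = 1e-10)$c_star,
               critical_value_independent(alpha, 0.4), tolerance = 1e-8)
})

test_that("fwer critical values recover Sidak, the degenerate pair and the example", {
  m_ind <- two_pop_model(0.5, "independent")
  expect_equal(fwer_critical_value(m_ind, alpha)$c_star,
               sidak_critical_value(alpha, 2), tolerance = 1e-7)
  m_same <- joint_null_model(matrix(1, 2, 2), labels = c("1", "2"))
  expect_equal(fwer_critical_value(m_same, alpha)$c_star,
               stats::qnorm(0.975), tolerance = 1e-6)
  expect_lt(abs(fwer_critical_value(m22, alpha)$c_star - 2.23), 0.01)
})

test_that("adjusted p-values are dual to the critical value", {
  cv <- pwer_critical_value(s22, m22, alpha)
  p_at_c <- adjusted_p_values(s22, m22, c("1" = cv$c_star, "2" = cv$c_star))
  expect_equal(p_at_c$p_pwer, rep(alpha, 2), tolerance = 1e-7)

  p_inf <- adjusted_p_values(s22, m22, c("1" = Inf, "2" = 0))
  expect_equal(p_inf$p_pwer[1], 0)

  p <- adjusted_p_values(s22, m22, c("1" = 2.2, "2" = 1.0))
  expect_lt(p$p_pwer[1], alpha)   # 2.2 >= c* ~ 2.03: rejected
  expect_gt(p$p_pwer[2], alpha)

  expect_error(adjusted_p_values(s22, m22, c("1" = 2.2)), "missing")
})

test_that("weighted thresholds keep the duality p_j <= alpha iff z_j >= w_j c*", {
  w <- c(1.2, 0.8)
  cv <- pwer_critical_value(s22, m22, alpha, weights = w)
  expect_lte(cv$achieved, alpha + 1e-8)
  expect_equal(unname(cv$thresholds), w * cv$c_star)
  for (j in 1:2) {
    z <- numeric(2); z[j] <- cv$thresholds[j] + 1e-6; z[-j] <- 0
    p <- adjusted_p_values(s22, m22, stats::setNames(z, c("1", "2")), weights = w)
    expect_lte(p$p_pwer[j], alpha + 1e-6)
    z[j] <- cv$thresholds[j] - 1e-3
    p <- adjusted_p_values(s22, m22, stats::setNames(z, c("1", "2")), weights = w)
    expect_gt(p$p_pwer[j], alpha)
  }
})

test_that("complementary PWER matches its two-population identity and limits", {
  # removing the intersection leaves two weighted marginal tails
  for (c in c(1.8, 2.0, 2.4)) {
    expect_equal(complementary_pwer(s22, m22, "1+2", c),
                 0.5 * stats::pnorm(c, lower.tail = FALSE) * 2,
                 tolerance = 1e-12)
  }
  expect_equal(complementary_pwer(s22, m22, "1+2", Inf), 0)
  expect_error(complementary_pwer(population_structure(c("1+2" = 1)),
                                  m22, "1+2", 2), "empty")
})

test_that("the nested worked example reproduces d*, the bound and the strata FWER", {
  d <- complementary_critical_value(nested_s, nested_m, "1+2+3", alpha)
  expect_lt(abs(d - 2.037), 1e-3)
  expect_lt(abs(joint_tail(nested_m, 1:3, d) - 0.0572), 5e-4)
  cv <- pwer_critical_value(nested_s, nested_m, alpha)
  expect_lt(abs(joint_tail(nested_m, 1:3, cv$c_star) - 0.0566), 5e-4)
})

test_that("strata error reports respect all analytic bounds", {
  rep <- strata_error_report(nested_s, nested_m, alpha)
  expect_equal(nrow(rep), 3)
  bounds <- pmin(rep$bound_prevalence,
                 pmin(rep$bound_alpha_tilde, rep$bound_bonferroni))
  expect_true(all(rep$fwer_at_cstar <= bounds + 1e-8))
  # singleton stratum: its FWER cannot exceed alpha
  expect_lte(rep$fwer_at_cstar[rep$stratum == "1"], alpha + 1e-8)
  expect_lt(abs(rep$fwer_at_dstar[rep$stratum == "1+2+3"] - 0.0572), 5e-4)
})

test_that("PWER never exceeds FWER and matches it for one shared population", {
  set.seed(41)
  for (rep in 1:3) {
    m_pop <- sample(2:4, 1)
    s <- random_structure(m_pop)
    model <- joint_null_model(random_corr(m_pop),
                              labels = as.character(seq_len(m_pop)))
    for (c in c(1.5, 2.0, 2.5))
      expect_lte(pwer(s, model, c), fwer(model, c) + 1e-10)
  }
  # P = P1 = P2: a single stratum containing every population
  s_one <- population_structure(c("1+2" = 1))
  for (c in c(1.5, 2.0, 2.5))
    expect_equal(pwer(s_one, m22, c), fwer(m22, c), tolerance = 1e-12)
  cv_p <- pwer_critical_value(s_one, m22, alpha)
  cv_f <- fwer_critical_value(m22, alpha)
  expect_equal(cv_p$c_star, cv_f$c_star, tolerance = 1e-6)
})

test_that("c* is bounded below by the marginal quantile and pwer decreases in c", {
  set.seed(53)
  for (rep in 1:3) {
    m_pop <- sample(2:3, 1)
    s <- random_structure(m_pop)
    model <- joint_null_model(random_corr(m_pop),
                              labels = as.character(seq_len(m_pop)))
    cv <- pwer_critical_value(s, model, alpha)
    expect_gte(cv$c_star, stats::qnorm(1 - alpha) - 1e-9)
    grid <- seq(1, 3, by = 0.2)
    vals <- vapply(grid, function(c) pwer(s, model, c), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("strata with no true-null hypothesis contribute nothing", {
  # only H1 true: PWER = (pi_{1} + pi_{12}) P(Z1 >= c)
  for (c in c(1.8, 2.2))
    expect_equal(pwer(s22, m22, c, truth = 1),
                 0.6 * stats::pnorm(c, lower.tail = FALSE), tolerance = 1e-12)
  # no true nulls: nothing can be falsely rejected
  expect_equal(pwer(s22, m22, 1.5, truth = integer(0)), 0)
})

test_that("the strata-FWER approximation error shrinks linearly in the prevalence", {
  ratios <- vapply(c(0.02, 0.01, 0.005, 0.0025), function(eps) {
    p <- c(0.75, 0.24) / 0.99 * (1 - eps)
    s <- population_structure(c("1" = p[1], "1+2" = p[2], "1+2+3" = eps))
    m <- nested_model(s)
    cs <- pwer_critical_value(s, m, alpha)$c_star
    d <- complementary_critical_value(s, m, "1+2+3", alpha)
    abs(joint_tail(m, 1:3, cs) - joint_tail(m, 1:3, d)) / eps
  }, numeric(1))
  expect_true(all(is.finite(ratios)))
  expect_true(all(ratios < 0.2))                 # bounded linear rate
  expect_lt(max(ratios) / min(ratios), 1.5)      # and roughly constant
})
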