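# Independent Monte-Carlo oracles used across the suite.

# Brute-force PWER at threshold c: draw the joint statistics, count for each
# stratum whether any relevant (true-null) statistic exceeds its threshold,
# and average weighted by the stratum prevalences.  Returns the estimate and
# its Monte-Carlo standard error.
mc_pwer_oracle <- function(structure, model, c, n_draws = 1e5, seed = 1,
                           weights = NULL) {
  set.seed(seed)
  Z <- if (is.finite(model$df))
    mvtnorm::rmvt(n_draws, sigma = model$correlation, df = round(model$df))
  else
    mvtnorm::rmvnorm(n_draws, sigma = model$correlation)
  w <- if (is.null(weights)) rep(1, model$k) else weights
  rel <- lapply(structure$sets, function(J)
    which(vapply(model$affects, function(a) any(a %in% J), logical(1))))
  ind <- vapply(rel, function(idx)
    rowSums(Z[, idx, drop = FALSE] >= rep(w[idx] * c, each = n_draws)) > 0,
    logical(n_draws))
  per_rep <- as.numeric(ind %*% as.numeric(structure$strata))
  list(estimate = mean(per_rep), se = stats::sd(per_rep) / sqrt(n_draws))
}

# random valid population structure with m populations (fixed RNG state of
# the caller decides the draw)
random_structure <- function(m, n_strata = NULL) {
  subsets <- popwise:::.all_subsets(m)
  if (is.null(n_strata)) n_strata <- sample(seq(m, length(subsets)), 1)
  pick <- sort(sample(seq_along(subsets), n_strata))
  # make sure every population index appears somewhere
  while (!all(seq_len(m) %in% unlist(subsets[pick])))
    pick <- sort(sample(seq_along(subsets), n_strata))
  p <- stats::rgamma(n_strata, 2)
  p <- p / sum(p)
  population_structure(stats::setNames(p, format_stratum(subsets[pick])))
}

# random positive-definite correlation matrix
random_corr <- function(k) {
  A <- matrix(stats::rnorm(k * k), k)
  stats::cov2cor(crossprod(A) + diag(k) * 0.5)
}

# subset t-statistics via stats::lm, the reference least-squares route
lm_subset_statistics <- function(data, design) {
  l <- design$l
  data$stratum <- factor(data$stratum, levels = as.character(seq_len(l)))
  data$treated <- as.numeric(!(data$arm %in% c("C", "control")))
  fit <- stats::lm(outcome ~ 0 + stratum + stratum:treated, data = data)
  theta_idx <- l + seq_len(l)   # interaction coefficients
  subsets <- popwise:::.all_subsets(l)
  W <- t(vapply(subsets, function(s) {
    w <- numeric(l)
    w[s] <- design$prevalences[s] / sum(design$prevalences[s])
    w
  }, numeric(l)))
  est <- as.numeric(W %*% stats::coef(fit)[theta_idx])
  V <- stats::vcov(fit)[theta_idx, theta_idx]
  se <- sqrt(diag(W %*% V %*% t(W)))
  stats::setNames(est / se, format_stratum(subsets))
}
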