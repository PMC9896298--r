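## Simultaneous confidence intervals dual to the PWER test.

#' Simultaneous confidence intervals with average simultaneous coverage
#'
#' Wald-type intervals dual to the PWER-calibrated single-step test: with
#' the one-sided critical value \eqn{c^*} solving \eqn{\mathrm{PWER} =
#' \alpha}, the lower bounds are \eqn{\tilde\theta_i = \hat\theta_i - c^*
#' \mathrm{SE}_i} (upper bounds analogously).  Two-sided intervals intersect
#' the two one-sided intervals and are calibrated at \eqn{\alpha/2} per
#' side, doubling the non-coverage of each one-sided bound.  The intervals
#' control the *average simultaneous coverage*: for a randomly drawn
#' patient, the probability that all bounds relevant to the patient's
#' stratum cover their parameters is at least \eqn{1 - \alpha}.
#'
#' @param estimates named (or model-ordered) effect estimates
#'   \eqn{\hat\theta_i}, one per hypothesis.
#' @param se standard errors (positive), same length.
#' @param structure a [population_structure()].
#' @param model a [joint_null_model()] for the Wald statistics.
#' @param alpha non-coverage level.
#' @param side \code{"lower"}, \code{"upper"} or \code{"two_sided"}.
#' @return a data frame of class \code{"pwer_sci"} with columns
#'   \code{hypothesis}, \code{estimate}, \code{se}, \code{lower},
#'   \code{upper}; the calibrated threshold is attached as attribute
#'   \code{c_star}.
#' @examples
#' s <- population_structure(c("1" = 0.4, "2" = 0.4, "1+2" = 0.2))
#' m <- two_pop_model(0.2, "unequal_treatments")
#' pwer_sci(c(0.3, 0.1), c(0.1, 0.1), s, m, side = "lower")
#' @export
pwer_sci <- function(estimates, se, structure, model, alpha = 0.025,
                     side = c("lower", "upper", "two_sided")) {
  side <- match.arg(side)
  if (!is.null(names(estimates))) {
    idx <- match(model$labels, names(estimates))
    if (anyNA(idx)) stop("estimates are missing hypotheses")
    estimates <- estimates[idx]
    se <- se[idx]
  }
  stopifnot(length(estimates) == model$k, length(se) == model$k)
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be positive")
  level <- if (side == "two_sided") alpha / 2 else alpha
  c_star <- pwer_critical_value(structure, model, alpha = level)$c_star
  lower <- if (side == "upper") rep(-Inf, model$k) else estimates - c_star * se
  upper <- if (side == "lower") rep(Inf, model$k) else estimates + c_star * se
  out <- data.frame(hypothesis = model$labels, estimate = as.numeric(estimates),
                    se = as.numeric(se), lower = lower, upper = upper,
                    row.names = NULL)
  attr(out, "c_star") <- c_star
  attr(out, "side") <- side
  attr(out, "alpha") <- alpha
  class(out) <- c("pwer_sci", "data.frame")
  out
}

#' Monte-Carlo check of the average simultaneous coverage
#'
#' Simulates standardized estimates from the joint model shifted by the true
#' effects, forms the dual bounds and returns the prevalence-weighted
#' probability that, within each stratum, all relevant bounds cover their
#' parameters:
#' \deqn{\sum_J \pi_J \, P_\theta(\tilde\theta_j \le \theta_j
#'   \text{ for all } j \in J) \ge 1 - \alpha.}
#' Wald bounds are shift-invariant, so the coverage does not depend on
#' \code{theta}; the argument is exposed to make that property checkable.
#'
#' @inheritParams pwer_sci
#' @param theta true effect vector (on the standardized statistic scale).
#' @param n_reps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return a list with \code{coverage}, \code{mc_se}, \code{c_star},
#'   \code{side}.
#' @export
sci_coverage <- function(structure, model, theta = rep(0, model$k),
                         alpha = 0.025, side = c("lower", "upper", "two_sided"),
                         n_reps = 10000, seed = 1) {
  side <- match.arg(side)
  stopifnot(length(theta) == model$k, n_reps >= 1000)
  level <- if (side == "two_sided") alpha / 2 else alpha
  c_star <- pwer_critical_value(structure, model, alpha = level)$c_star
  set.seed(seed)
  ## standardized estimation errors (theta_hat - theta)/SE under the model
  E <- if (is.finite(model$df))
    mvtnorm::rmvt(n_reps, sigma = model$correlation, df = as.integer(round(model$df)))
  else
    mvtnorm::rmvnorm(n_reps, sigma = model$correlation)
  ## lower bound covers iff E_j <= c*; upper iff E_j >= -c*; two-sided both
  cov_j <- switch(side,
                  lower = E <= c_star,
                  upper = E >= -c_star,
                  two_sided = abs(E) <= c_star)
  rel <- .relevant_hypotheses(structure, model)
  ind <- vapply(rel, function(idx)
    rowSums(!cov_j[, idx, drop = FALSE]) == 0, logical(n_reps))
  per_rep <- as.numeric(ind %*% as.numeric(structure$strata))
  list(coverage = mean(per_rep),
       mc_se = stats::sd(per_rep) / sqrt(n_reps),
       c_star = c_star, side = side,
       per_stratum = stats::setNames(colMeans(ind), names(structure$strata)))
}
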