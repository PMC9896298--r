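## Core population-wise error rate machinery.
##
## The PWER at threshold c is the prevalence-weighted average, over the
## disjoint strata P_J, of the probability that at least one *true* null
## hypothesis affecting P_J is rejected:
##
##   PWER(c) = sum_J pi_J P( max_{i in rel(J), i null} Z_i >= c_i ),
##
## with per-hypothesis thresholds c_i = w_i c (equal weights by default) and
## rel(J) the hypotheses whose target population intersects stratum P_J.

## hypotheses relevant to each stratum (list parallel to structure$sets)
.relevant_hypotheses <- function(structure, model) {
  covered <- sort(unique(unlist(model$affects)))
  if (structure$m > max(covered) || !all(seq_len(structure$m) %in% covered))
    stop("model hypotheses do not cover all population indices in the structure")
  lapply(structure$sets, function(J)
    which(vapply(model$affects, function(a) any(a %in% J), logical(1))))
}

.truth_indices <- function(model, truth) {
  if (is.null(truth)) return(seq_len(model$k))
  idx <- if (is.character(truth)) match(truth, model$labels) else as.integer(truth)
  if (anyNA(idx) || any(idx < 1L) || any(idx > model$k))
    stop("truth configuration refers to unknown hypotheses")
  sort(unique(idx))
}

.check_weights <- function(model, weights) {
  if (is.null(weights)) return(rep(1, model$k))
  if (length(weights) != model$k || any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be ", model$k, " positive numbers")
  as.numeric(weights)
}

#' Population-wise error rate at a threshold
#'
#' Evaluates the PWER for a common critical value \code{c} (optionally with
#' per-hypothesis weights, i.e. thresholds \eqn{c_i = w_i c}) under a given
#' truth configuration.  Strata whose relevant true-null set is empty
#' contribute zero.
#'
#' @param structure a [population_structure()].
#' @param model a [joint_null_model()] whose hypothesis labels cover all
#'   population indices of \code{structure}.
#' @param c common critical value on the statistic scale.
#' @param truth indices (or labels) of the hypotheses whose nulls are true;
#'   default all (the global null, which is least favourable for pivotal
#'   statistics).
#' @param weights optional positive per-hypothesis weights \eqn{w_i}.
#' @return the PWER, a probability.
#' @examples
#' s <- population_structure(c("1" = 0.4, "2" = 0.4, "1+2" = 0.2))
#' m <- two_pop_model(0.2, "unequal_treatments")
#' pwer(s, m, c = 2.03)
#' @export
pwer <- function(structure, model, c, truth = NULL, weights = NULL) {
  stopifnot(inherits(structure, "population_structure"),
            inherits(model, "joint_null_model"), length(c) == 1L)
  rel <- .relevant_hypotheses(structure, model)
  null_idx <- .truth_indices(model, truth)
  w <- .check_weights(model, weights)
  contrib <- vapply(rel, function(idx) {
    idx <- intersect(idx, null_idx)
    .joint_exceed(model, idx, w[idx] * c)  # 0 for empty idx
  }, numeric(1))
  sum(structure$strata * contrib)
}

#' Family-wise error rate at a threshold
#'
#' \eqn{P(\max_i Z_i \ge w_i c)} over all true null hypotheses.
#'
#' @inheritParams pwer
#' @return the FWER, a probability.
#' @export
fwer <- function(model, c, truth = NULL, weights = NULL) {
  stopifnot(inherits(model, "joint_null_model"))
  idx <- .truth_indices(model, truth)
  w <- .check_weights(model, weights)
  .joint_exceed(model, idx, w[idx] * c)
}

## bracketed root of f(c) = target with f strictly decreasing; expands the
## bracket if needed, errors with diagnostics when no sign change is found
.solve_decreasing <- function(f, target, lower, upper, tol = 1e-9, what = "critical value") {
  flo <- f(lower); fhi <- f(upper)
  tries <- 0L
  while (flo < target && tries < 50L) { lower <- lower - 0.5; flo <- f(lower); tries <- tries + 1L }
  tries <- 0L
  while (fhi > target && tries < 50L) { upper <- upper + 0.5; fhi <- f(upper); tries <- tries + 1L }
  if (flo < target || fhi > target)
    stop(sprintf("root for %s not bracketed: f(%.4f) = %.3g, f(%.4f) = %.3g, target %.3g",
                 what, lower, flo, upper, fhi, target))
  stats::uniroot(function(x) f(x) - target, lower = lower, upper = upper,
                 f.lower = flo - target, f.upper = fhi - target, tol = tol)$root
}

#' PWER-controlling critical value
#'
#' Finds the smallest common critical value \eqn{c^*} (with per-hypothesis
#' thresholds \eqn{c_i^* = w_i c^*}) such that the PWER does not exceed
#' \code{alpha}, by bracketed root solving.  With equal weights and identical
#' marginals, \eqn{c^*} can never fall short of the marginal
#' \eqn{(1-\alpha)}-quantile, and it is bounded above by the Bonferroni
#' quantile; the initial bracket uses both, expanding if weights move the
#' root outside it.
#'
#' @inheritParams pwer
#' @param alpha target PWER level in \eqn{(0, 1)}.
#' @param tol absolute tolerance on \eqn{c^*}.
#' @return an object of class \code{"pwer_critval"}: list with \code{c_star},
#'   \code{thresholds} (\eqn{w_i c^*}), \code{weights}, \code{achieved},
#'   \code{alpha}, \code{bracket}, \code{tol}, and the inputs.
#' @examples
#' s <- population_structure(c("1" = 0.4, "2" = 0.4, "1+2" = 0.2))
#' m <- two_pop_model(0.2, "unequal_treatments")
#' pwer_critical_value(s, m, alpha = 0.025)   # approx 2.03
#' @export
pwer_critical_value <- function(structure, model, alpha = 0.025, truth = NULL,
                                weights = NULL, tol = 1e-9) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  w <- .check_weights(model, weights)
  lower <- .marginal_quantile(model, 1 - alpha) - 1e-9
  upper <- .marginal_quantile(model, 1 - alpha / model$k) + 1
  f <- function(c) pwer(structure, model, c, truth = truth, weights = w)
  c_star <- .solve_decreasing(f, alpha, lower, upper, tol = tol, what = "PWER critical value")
  res <- list(c_star = c_star,
              thresholds = stats::setNames(w * c_star, model$labels),
              weights = stats::setNames(w, model$labels),
              achieved = f(c_star), alpha = alpha,
              bracket = c(lower, upper), tol = tol,
              criterion = "PWER", structure = structure, model = model, truth = truth)
  class(res) <- "pwer_critval"
  res
}

#' FWER-controlling critical value
#'
#' Solves \eqn{P(\max_i Z_i \ge c) = \alpha} over all (true-null) statistics
#' of the model — the single-step max-statistic threshold.
#'
#' @inheritParams pwer_critical_value
#' @return an object of class \code{"pwer_critval"} (criterion "FWER").
#' @export
fwer_critical_value <- function(model, alpha = 0.025, truth = NULL,
                                weights = NULL, tol = 1e-9) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  w <- .check_weights(model, weights)
  lower <- .marginal_quantile(model, 1 - alpha) - 1e-9
  upper <- .marginal_quantile(model, 1 - alpha / model$k) + 1
  f <- function(c) fwer(model, c, truth = truth, weights = w)
  c_star <- .solve_decreasing(f, alpha, lower, upper, tol = tol, what = "FWER critical value")
  res <- list(c_star = c_star,
              thresholds = stats::setNames(w * c_star, model$labels),
              weights = stats::setNames(w, model$labels),
              achieved = f(c_star), alpha = alpha,
              bracket = c(lower, upper), tol = tol,
              criterion = "FWER", structure = NULL, model = model, truth = truth)
  class(res) <- "pwer_critval"
  res
}

#' @export
print.pwer_critval <- function(x, ...) {
  cat(sprintf("%s-controlling critical value (alpha = %g)\n", x$criterion, x$alpha))
  cat(sprintf("  c* = %.6f   achieved %s = %.6g\n", x$c_star, x$criterion, x$achieved))
  if (any(x$weights != 1)) {
    cat("  weighted thresholds c_i* = w_i c*:\n")
    print(round(x$thresholds, 6))
  }
  invisible(x)
}

#' @export
coef.pwer_critval <- function(object, ...) object$thresholds

#' @export
summary.pwer_critval <- function(object, ...) {
  out <- list(critval = object,
              strata_report = if (object$criterion == "PWER" &&
                                  all(object$weights == 1))
                strata_error_report(object$structure, object$model, object$alpha)
              else NULL)
  class(out) <- "summary.pwer_critval"
  out
}

#' @export
print.summary.pwer_critval <- function(x, ...) {
  print(x$critval)
  if (!is.null(x$strata_report)) {
    cat("\nStrata-wise FWER report:\n")
    print(x$strata_report, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn pwer_sci \code{confint} method: simultaneous confidence
#'   intervals dual to a calibrated PWER critical value.
#' @param object a \code{"pwer_critval"} object (equal weights).
#' @param parm ignored.
#' @param level ignored; the level is \code{1 - alpha} of the calibration.
#' @export
confint.pwer_critval <- function(object, parm, level, estimates, se,
                                 side = c("two_sided", "lower", "upper"), ...) {
  side <- match.arg(side)
  if (object$criterion != "PWER" || is.null(object$structure))
    stop("confidence intervals require a PWER calibration with its structure")
  pwer_sci(estimates, se, object$structure, object$model,
           alpha = object$alpha, side = side)
}

#' PWER-adjusted p-values
#'
#' The adjusted p-value of hypothesis \eqn{j} is the smallest level at which
#' the calibrated procedure rejects it: the PWER evaluated at threshold
#' \eqn{z_j^{obs}} (for weighted thresholds, at \eqn{c = z_j^{obs} / w_j}).
#' \code{p_j <= alpha} if and only if \eqn{z_j^{obs} \ge w_j c^*}.
#'
#' @inheritParams pwer
#' @param z_obs named (or model-ordered) vector of observed statistics, one
#'   per hypothesis.
#' @return data frame with columns \code{hypothesis}, \code{z_obs},
#'   \code{p_pwer}.
#' @export
adjusted_p_values <- function(structure, model, z_obs, truth = NULL, weights = NULL) {
  w <- .check_weights(model, weights)
  if (!is.null(names(z_obs))) {
    idx <- match(model$labels, names(z_obs))
    if (anyNA(idx)) stop("z_obs is missing hypotheses: ",
                         paste(model$labels[is.na(idx)], collapse = ", "))
    z_obs <- z_obs[idx]
  }
  if (length(z_obs) != model$k || anyNA(z_obs))
    stop("one observed statistic per hypothesis is required")
  p <- vapply(seq_len(model$k), function(j)
    min(1, pwer(structure, model, z_obs[j] / w[j], truth = truth, weights = w)),
    numeric(1))
  data.frame(hypothesis = model$labels, z_obs = as.numeric(z_obs),
             p_pwer = p, row.names = NULL)
}

#' Complementary PWER of a stratum
#'
#' The PWER recomputed after removing stratum \eqn{P_J} from the population
#' and renormalizing the remaining prevalences:
#' \deqn{\mathrm{cPWER}_J(c) = \sum_{J' \ne J} \tilde\pi_{J'}
#'   P(\max_{j \in J'} Z_j \ge c), \qquad
#'   \tilde\pi_{J'} = \pi_{J'} / (1 - \pi_J).}
#' Its level-\eqn{\alpha} root \eqn{d_J^*} approximates the strata-wise FWER
#' of \eqn{P_J} under full PWER control when \eqn{\pi_J} is small.
#'
#' @inheritParams pwer
#' @param J stratum (label or integer index set) to remove.
#' @return a probability ([complementary_pwer()]) or the threshold
#'   \eqn{d_J^*} ([complementary_critical_value()]).
#' @export
complementary_pwer <- function(structure, model, J, c, truth = NULL, weights = NULL) {
  lab <- if (is.character(J)) format_stratum(parse_stratum(J)[[1]]) else format_stratum(J)
  pi_J <- if (lab %in% names(structure$strata)) structure$strata[[lab]] else 0
  if (pi_J >= 1 - 1e-12) stop("complement of stratum ", lab, " is empty")
  keep <- names(structure$strata) != lab
  rel <- .relevant_hypotheses(structure, model)[keep]
  null_idx <- .truth_indices(model, truth)
  w <- .check_weights(model, weights)
  contrib <- vapply(rel, function(idx) {
    idx <- intersect(idx, null_idx)
    .joint_exceed(model, idx, w[idx] * c)
  }, numeric(1))
  sum(structure$strata[keep] / (1 - pi_J) * contrib)
}

#' @rdname complementary_pwer
#' @param alpha target level.
#' @param tol root tolerance.
#' @export
complementary_critical_value <- function(structure, model, J, alpha = 0.025,
                                         truth = NULL, weights = NULL, tol = 1e-9) {
  w <- .check_weights(model, weights)
  lower <- .marginal_quantile(model, 1 - alpha) - 1
  upper <- .marginal_quantile(model, 1 - alpha / model$k) + 1
  .solve_decreasing(function(c) complementary_pwer(structure, model, J, c,
                                                   truth = truth, weights = w),
                    alpha, lower, upper, tol = tol,
                    what = "complementary-PWER threshold")
}

#' Strata-wise FWER report under PWER control
#'
#' For each stratum \eqn{P_J}, the strata-wise FWER
#' \eqn{\mathrm{FWER}_J(c) = P(\max_{j \in \mathrm{rel}(J)} Z_j \ge c)}
#' evaluated at the PWER-calibrated \eqn{c^*}, together with its analytic
#' bounds: \eqn{\alpha/\pi_J}; \eqn{\tilde\alpha_J = P(\max_{j} Z_j \ge
#' z_\alpha)} (from \eqn{c^* \ge z_\alpha}); the Bonferroni bound
#' \eqn{\min(|J|\alpha, 1)}; and the small-\eqn{\pi_J} approximation
#' \eqn{\mathrm{FWER}_J(d_J^*)} with \eqn{d_J^*} the complementary-PWER
#' threshold.
#'
#' @inheritParams pwer_critical_value
#' @return data frame, one row per stratum: \code{stratum},
#'   \code{prevalence}, \code{fwer_at_cstar}, \code{d_star},
#'   \code{fwer_at_dstar}, \code{bound_prevalence}, \code{bound_alpha_tilde},
#'   \code{bound_bonferroni}.  The calibrated \code{c_star} and \code{alpha}
#'   are attached as attributes.
#' @export
strata_error_report <- function(structure, model, alpha = 0.025) {
  cv <- pwer_critical_value(structure, model, alpha = alpha)
  rel <- .relevant_hypotheses(structure, model)
  z_alpha <- .marginal_quantile(model, 1 - alpha)
  rows <- lapply(seq_along(structure$sets), function(s) {
    idx <- rel[[s]]
    fw <- function(c) .joint_exceed(model, idx, rep(c, length(idx)))
    d_star <- complementary_critical_value(structure, model, structure$sets[[s]],
                                           alpha = alpha)
    data.frame(stratum = names(structure$strata)[s],
               prevalence = as.numeric(structure$strata[s]),
               fwer_at_cstar = fw(cv$c_star),
               d_star = d_star,
               fwer_at_dstar = fw(d_star),
               bound_prevalence = alpha / as.numeric(structure$strata[s]),
               bound_alpha_tilde = fw(z_alpha),
               bound_bonferroni = min(length(idx) * alpha, 1))
  })
  out <- do.call(rbind, rows)
  attr(out, "c_star") <- cv$c_star
  attr(out, "alpha") <- alpha
  out
}
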