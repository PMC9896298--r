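## Design calculators for two overlapping populations.

#' Closed-form PWER critical value for two independent samples
#'
#' Two overlapping populations tested with one treatment in two independent
#' samples (independent standard-normal statistics).  Solving
#' \eqn{\mathrm{PWER} = (1-\pi)\{1-\Phi(c)\} + \pi\{1-\Phi(c)^2\} = \alpha}
#' for \eqn{\pi = \pi_{\{1,2\}} > 0} gives
#' \deqn{c_P^* = \Phi^{-1}\!\left(
#'   \frac{-(1-\pi) + \sqrt{(1-\pi)^2 + 4\pi(1-\alpha)}}{2\pi}\right),}
#' decreasing to the unadjusted \eqn{\Phi^{-1}(1-\alpha)} as \eqn{\pi
#' \downarrow 0} and increasing to the Šidák value as \eqn{\pi \uparrow 1}.
#'
#' @param alpha one-sided level.
#' @param pi12 intersection prevalence in \eqn{[0, 1]}.
#' @return the critical value.
#' @examples
#' critical_value_independent(0.025, 0.4)
#' @export
critical_value_independent <- function(alpha, pi12) {
  stopifnot(alpha > 0, alpha < 1, all(pi12 >= 0), all(pi12 <= 1))
  ifelse(pi12 == 0, stats::qnorm(1 - alpha),
         stats::qnorm((-(1 - pi12) + sqrt((1 - pi12)^2 + 4 * pi12 * (1 - alpha))) /
                        (2 * pmax(pi12, .Machine$double.eps))))
}

#' Šidák critical value for k independent statistics
#'
#' Solves \eqn{1 - \Phi(c)^k = \alpha}, i.e.
#' \eqn{c = \Phi^{-1}\{(1-\alpha)^{1/k}\}}.
#'
#' @param alpha one-sided level.
#' @param k number of independent statistics.
#' @export
sidak_critical_value <- function(alpha, k = 2) {
  stopifnot(alpha > 0, alpha < 1, k >= 1)
  stats::qnorm((1 - alpha)^(1 / k))
}

#' Sample-size inflation factor of a multiplicity-adjusted critical value
#'
#' For a marginal power of \eqn{1-\beta} the per-population sample size
#' scales with the square of \eqn{\Phi^{-1}(1-\beta) + c}; relative to the
#' unadjusted threshold \eqn{\Phi^{-1}(1-\alpha)} the required inflation is
#' \deqn{q_\alpha(c) = \left(\frac{\Phi^{-1}(1-\beta) + c}
#'   {\Phi^{-1}(1-\beta) + \Phi^{-1}(1-\alpha)}\right)^2.}
#' (The non-centrality per unit sample size cancels in the ratio.)
#'
#' @param c critical value (finite).
#' @param alpha one-sided level of the unadjusted reference.
#' @param beta type II error rate; marginal power is \eqn{1-\beta}.
#' @return the inflation factor \eqn{q_\alpha(c)}; 1 at the unadjusted
#'   threshold.
#' @examples
#' sample_size_inflation(2.23)   # about 1.20
#' sample_size_inflation(2.03)   # about 1.05
#' @export
sample_size_inflation <- function(c, alpha = 0.025, beta = 0.2) {
  stopifnot(all(is.finite(c)), alpha > 0, alpha < 1, beta > 0, beta < 1)
  ((stats::qnorm(1 - beta) + c) / (stats::qnorm(1 - beta) + stats::qnorm(1 - alpha)))^2
}

#' Symmetric two-population structure from the overlap size
#'
#' Equal complements \eqn{\pi_{\{1\}} = \pi_{\{2\}} = (1 - \pi_{\{1,2\}})/2}.
#' Degenerate strata (at \code{pi12 = 0} or \code{1}) are omitted.
#'
#' @param pi12 intersection prevalence.
#' @return a [population_structure()].
#' @export
two_pop_structure <- function(pi12) {
  stopifnot(pi12 >= 0, pi12 <= 1)
  p <- c("1" = (1 - pi12) / 2, "2" = (1 - pi12) / 2, "1+2" = pi12)
  population_structure(p[p > 0])
}

#' Critical-value and sample-size inflation curves over the overlap size
#'
#' For a grid of intersection prevalences, computes the PWER- and
#' FWER-controlling critical values of the chosen two-population scenario
#' (both populations of equal size) and the corresponding sample-size
#' inflation factors.  For the \code{"independent"} scenario the FWER value
#' is the Šidák constant and the PWER value has the closed form of
#' [critical_value_independent()]; the shared-control scenarios are solved
#' numerically with their correlation formulas.
#'
#' @param scenario \code{"independent"}, \code{"unequal_treatments"} or
#'   \code{"equal_treatments"}.
#' @param alpha one-sided level.
#' @param beta type II error rate for the inflation factors.
#' @param pi12 grid of intersection prevalences in \eqn{[0, 1]}.
#' @return a data frame of class \code{"inflation_curve"} with columns
#'   \code{pi12}, \code{c_pwer}, \code{c_fwer}, \code{q_pwer}, \code{q_fwer}.
#' @examples
#' curve <- inflation_curve("independent", pi12 = seq(0, 1, 0.25))
#' curve
#' @export
inflation_curve <- function(scenario = c("independent", "unequal_treatments",
                                         "equal_treatments"),
                            alpha = 0.025, beta = 0.2,
                            pi12 = seq(0, 1, by = 0.025)) {
  scenario <- match.arg(scenario)
  stopifnot(all(pi12 >= 0), all(pi12 <= 1))
  rows <- lapply(pi12, function(p) {
    s <- two_pop_structure(p)
    if (scenario == "independent") {
      c_p <- critical_value_independent(alpha, p)
      c_f <- sidak_critical_value(alpha, 2)
    } else {
      m <- two_pop_model(p, scenario)
      c_p <- if (p == 1)  # single stratum: PWER = FWER = marginal level
        fwer_critical_value(m, alpha)$c_star
      else pwer_critical_value(s, m, alpha)$c_star
      c_f <- fwer_critical_value(m, alpha)$c_star
    }
    data.frame(pi12 = p, c_pwer = c_p, c_fwer = c_f,
               q_pwer = sample_size_inflation(c_p, alpha, beta),
               q_fwer = sample_size_inflation(c_f, alpha, beta))
  })
  out <- do.call(rbind, rows)
  attr(out, "scenario") <- scenario
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  class(out) <- c("inflation_curve", "data.frame")
  out
}

#' @export
plot.inflation_curve <- function(x, which = c("inflation", "critical"), ...) {
  which <- match.arg(which)
  if (which == "inflation") {
    graphics::plot(x$pi12, x$q_fwer, type = "l", lty = 2,
                   xlab = expression(pi["{1,2}"]),
                   ylab = "sample size inflation factor",
                   ylim = range(c(x$q_pwer, x$q_fwer)), ...)
    graphics::lines(x$pi12, x$q_pwer, lty = 1)
    graphics::legend("bottomright", legend = c("PWER", "FWER"), lty = c(1, 2))
  } else {
    graphics::plot(x$pi12, x$c_fwer, type = "l", lty = 2,
                   xlab = expression(pi["{1,2}"]), ylab = "critical value",
                   ylim = range(c(x$c_pwer, x$c_fwer)), ...)
    graphics::lines(x$pi12, x$c_pwer, lty = 1)
    graphics::legend("bottomright", legend = c("PWER", "FWER"), lty = c(1, 2))
  }
  invisible(x)
}
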