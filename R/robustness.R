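## Robustness of PWER control to estimated prevalences.
##
## In practice the stratum prevalences are estimated from the recruited
## sample.  Plugging the multinomial MLEs into the calibration makes the
## critical value random; the study below measures how far the *true* PWER
## (true prevalences, conditional-on-counts correlation, estimated critical
## value) drifts from the nominal level.

#' Conditional correlation of the two-population statistics given counts
#'
#' The correlation of \eqn{(Z_1, Z_2)}, conditional on the realized stratum
#' counts \eqn{(n_{\{1\}}, n_{\{2\}}, n_{\{1,2\}})}, for the shared-control
#' scenarios.  With different treatments the statistics share only the
#' intersection control group and the weighted-mean estimator uses
#' prevalence weights (by default the multinomial MLEs from the counts):
#' \deqn{\rho = \frac{b_1 b_2 \cdot 3 / n_{\{1,2\}}}{\sqrt{V_1 V_2}}, \quad
#'   V_i = a_i^2 \frac{4}{n_{\{i\}}} + b_i^2 \frac{6}{n_{\{1,2\}}},}
#' with \eqn{a_i, b_i} the complement/intersection weights of population
#' \eqn{i}.  With equal treatments (pooled estimators, 1:1 everywhere)
#' \eqn{\rho = n_{\{1,2\}} / \sqrt{n_1 n_2}} for the population totals
#' \eqn{n_i = n_{\{i\}} + n_{\{1,2\}}}.  Both reduce to the closed-form
#' prevalence formulas when the counts match \eqn{N \pi_J} exactly and
#' \eqn{\pi_{\{1\}} = \pi_{\{2\}}}.
#'
#' @param counts named count vector with entries \code{"1"}, \code{"2"},
#'   \code{"1+2"}.
#' @param scenario \code{"unequal_treatments"} or \code{"equal_treatments"}.
#' @param weights optional prevalence weights (a [population_structure()])
#'   used for the weighted-mean estimator; default the MLEs from
#'   \code{counts}.
#' @return the conditional correlation (0 if the intersection is empty).
#' @export
conditional_corr_two_pop <- function(counts,
                                     scenario = c("unequal_treatments",
                                                  "equal_treatments"),
                                     weights = NULL) {
  scenario <- match.arg(scenario)
  g <- function(lab) if (lab %in% names(counts)) as.numeric(counts[[lab]]) else 0
  n1 <- g("1"); n2 <- g("2"); n12 <- g("1+2")
  if (n12 == 0) return(0)
  if (scenario == "equal_treatments")
    return(n12 / sqrt((n1 + n12) * (n2 + n12)))
  if (is.null(weights)) {
    N <- n1 + n2 + n12
    p1 <- n1 / N; p2 <- n2 / N; p12 <- n12 / N
  } else {
    gs <- function(lab) if (lab %in% names(weights$strata)) weights$strata[[lab]] else 0
    p1 <- gs("1"); p2 <- gs("2"); p12 <- gs("1+2")
  }
  b <- c(p12 / (p1 + p12), p12 / (p2 + p12))
  a <- 1 - b
  vterm <- function(a_i, b_i, n_c) {
    v <- b_i^2 * 6 / n12
    if (a_i > 0) v <- v + a_i^2 * 4 / n_c   # zero-weight empty strata drop out
    v
  }
  V1 <- vterm(a[1], b[1], n1); V2 <- vterm(a[2], b[2], n2)
  if (V1 <= 0 || V2 <= 0) return(0)
  (b[1] * b[2] * 3 / n12) / sqrt(V1 * V2)
}

## true PWER at threshold c for true prevalences p = (p1, p2, p12), given
## which populations were tested and the conditional correlation rho
.true_pwer_two_pop <- function(p, c, rho, tested) {
  tail1 <- stats::pnorm(c, lower.tail = FALSE)
  both <- all(tested)
  tp <- 0
  if (tested[1]) tp <- tp + p[1] * tail1
  if (tested[2]) tp <- tp + p[2] * tail1
  if (any(tested))
    tp <- tp + p[3] * (if (both)
      1 - .mv_cdf(c(c, c), matrix(c(1, rho, rho, 1), 2)) else tail1)
  tp
}

#' PWER robustness study under estimated prevalences
#'
#' For each true prevalence point \eqn{(\pi_{\{1\}}, \pi_{\{2\}})} (with
#' \eqn{\pi_{\{1,2\}} = 1 - \pi_{\{1\}} - \pi_{\{2\}}}): draw stratum counts
#' from the multinomial, estimate the prevalences by maximum likelihood,
#' calibrate the critical value from the estimates and the
#' conditional-on-counts correlation, then evaluate the *true* PWER by
#' plugging that critical value into the PWER with the true prevalences and
#' the same conditional correlation.  A population with zero recruited
#' patients is not tested in that replicate: its hypothesis drops from both
#' the calibration and the true-PWER evaluation.
#'
#' Replicate computations are memoized on the realized count vector (counts
#' repeat heavily at small \code{N}), which leaves the estimator unchanged.
#'
#' @param scenario \code{"unequal_treatments"} or \code{"equal_treatments"}.
#' @param grid data frame with columns \code{pi1}, \code{pi2} (complement
#'   prevalences); default the lattice \eqn{\{0.05, 0.1, \dots\}} with
#'   \eqn{\pi_{\{1\}} + \pi_{\{2\}} \le 0.95}.
#' @param N trial sample size per replicate.
#' @param alpha target PWER level.
#' @param n_reps multinomial replicates per grid point.
#' @param seed RNG seed.
#' @param min_prevalence optional floor applied to the estimated prevalences.
#' @return data frame with columns \code{pi1}, \code{pi2}, \code{pi12},
#'   \code{N}, \code{mean_true_pwer}, \code{se}, \code{sd_single},
#'   \code{n_reps}.
#' @export
prevalence_robustness <- function(scenario = c("unequal_treatments",
                                               "equal_treatments"),
                                  grid = NULL, N = 50, alpha = 0.025,
                                  n_reps = 10000, seed = 1,
                                  min_prevalence = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(N >= 1, n_reps >= 100)
  if (is.null(grid)) {
    g <- seq(0.05, 0.90, by = 0.05)
    grid <- expand.grid(pi1 = g, pi2 = g)
    grid <- grid[grid$pi1 + grid$pi2 <= 0.95, ]
  }
  stopifnot(all(c("pi1", "pi2") %in% names(grid)))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    p_true <- c(grid$pi1[r], grid$pi2[r], 1 - grid$pi1[r] - grid$pi2[r])
    stopifnot(all(p_true >= -1e-12))
    draws <- stats::rmultinom(n_reps, N, p_true)
    key <- paste(draws[1, ], draws[2, ], draws[3, ])
    tab <- table(key)
    uniq <- strsplit(names(tab), " ")
    vals <- vapply(uniq, function(u)
      .plugin_true_pwer(as.numeric(u), p_true, scenario, alpha, min_prevalence),
      numeric(1))
    freq <- as.numeric(tab)
    mean_tp <- sum(freq * vals) / n_reps
    sd_tp <- sqrt(sum(freq * (vals - mean_tp)^2) / (n_reps - 1))
    data.frame(pi1 = p_true[1], pi2 = p_true[2], pi12 = p_true[3], N = N,
               mean_true_pwer = mean_tp, se = sd_tp / sqrt(n_reps),
               sd_single = sd_tp, n_reps = n_reps)
  })
  do.call(rbind, rows)
}

## one replicate: estimate prevalences from the counts, calibrate, evaluate
## the true PWER (counts ordered as strata "1", "2", "1+2")
.plugin_true_pwer <- function(cnt, p_true, scenario, alpha,
                              min_prevalence = NULL) {
  names(cnt) <- c("1", "2", "1+2")
  n_pop <- c(cnt[[1]] + cnt[[3]], cnt[[2]] + cnt[[3]])
  tested <- n_pop > 0
  if (!any(tested)) return(0)  # nothing tested, nothing rejected
  est <- if (is.null(min_prevalence)) mle_prevalences(cnt[cnt > 0])
         else mle_prevalences(cnt, min_prevalence = min_prevalence)
  rho <- conditional_corr_two_pop(cnt, scenario, weights = est)
  z_single <- stats::qnorm(1 - alpha)
  if (sum(tested) == 1L) {
    c_hat <- z_single   # single hypothesis: marginal quantile
  } else {
    ge <- function(lab) if (lab %in% names(est$strata)) est$strata[[lab]] else 0
    f <- function(c) {
      (ge("1") + ge("2")) * stats::pnorm(c, lower.tail = FALSE) +
        ge("1+2") * (1 - .mv_cdf(c(c, c), matrix(c(1, rho, rho, 1), 2)))
    }
    c_hat <- .solve_decreasing(f, alpha, z_single - 1e-9,
                               stats::qnorm(1 - alpha / 2) + 1, tol = 1e-8,
                               what = "estimated-prevalence critical value")
  }
  .true_pwer_two_pop(p_true, c_hat, rho, tested)
}
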