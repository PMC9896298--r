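## Subject-level trial simulator: the synthetic-data backbone shared by the
## design calculators, the robustness study and the test-suite oracles.

#' Largest-remainder rounding of N * p
#'
#' Integer counts summing to \code{N} with proportions as close to \code{p}
#' as possible: floors first, then the remaining units go to the largest
#' fractional remainders (ties by index order).
#'
#' @param N total count.
#' @param p vector of proportions (summing to 1).
#' @return integer vector summing to \code{N}.
#' @export
largest_remainder <- function(N, p) {
  stopifnot(N >= 0, all(p >= 0), abs(sum(p) - 1) < 1e-8)
  exact <- N * p
  n <- floor(exact)
  left <- round(N - sum(n))
  if (left > 0) {
    extra <- order(exact - n, decreasing = TRUE)[seq_len(left)]
    n[extra] <- n[extra] + 1
  }
  as.integer(n)
}

## split a stratum count into arm counts per the scenario's allocation rule
.allocate_arms <- function(n, arms) {
  k <- length(arms)
  base <- largest_remainder(n, rep(1 / k, k))
  ## experimental arms round down on odd counts: give remainders to control
  ctrl <- which(arms == "C")
  if (length(ctrl) == 1L && sum(base) == n) {
    flo <- n %/% k
    extra <- n - flo * k
    base <- rep(flo, k)
    base[ctrl] <- base[ctrl] + extra
  }
  stats::setNames(base, arms)
}

#' Simulate subject-level trial data
#'
#' Generates one trial: stratum sizes are \code{N * pi_J} by
#' largest-remainder rounding (or a multinomial draw with
#' \code{random_membership = TRUE}), arms are allocated by the scenario's
#' rule, and outcomes are normal with the scenario's mean structure and
#' common standard deviation \code{sigma}.
#'
#' Scenarios: \describe{
#'   \item{\code{"umbrella"}}{disjoint strata (singleton labels), arm
#'     \code{"T<i>"} vs \code{"C"} 1:1 within stratum \eqn{i}; mean
#'     \code{mu[i] + effects[i]} on treatment.}
#'   \item{\code{"unequal_treatments"}}{two overlapping populations,
#'     different treatments, shared control: 1:1 (\code{T<i>} vs \code{C})
#'     in the complements, 1:1:1 (\code{T1}, \code{T2}, \code{C}) in the
#'     intersection; treatment \code{T<i>} adds \code{effects[i]}.}
#'   \item{\code{"equal_treatments"}}{one treatment in both populations:
#'     1:1 (\code{T1} vs \code{C}) in every stratum; \code{effects[1]} on
#'     treatment.}
#' }
#'
#' @param structure a [population_structure()].
#' @param scenario allocation scenario, see Details.
#' @param effects treatment effect per treatment index (umbrella: per
#'   stratum).
#' @param sigma residual standard deviation.
#' @param N total sample size.
#' @param seed optional RNG seed; same seed, same data.
#' @param random_membership draw stratum sizes from the multinomial instead
#'   of deterministic rounding.
#' @param mu baseline mean per stratum (recycled; default 0).
#' @return data frame with columns \code{subject_id}, \code{stratum},
#'   \code{arm}, \code{outcome}.
#' @examples
#' s <- population_structure(c("1" = 0.4, "2" = 0.4, "1+2" = 0.2))
#' head(simulate_trial(s, "unequal_treatments", effects = c(0, 0), N = 60, seed = 1))
#' @export
simulate_trial <- function(structure,
                           scenario = c("umbrella", "unequal_treatments",
                                        "equal_treatments"),
                           effects, sigma = 1, N, seed = NULL,
                           random_membership = FALSE, mu = 0) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(structure, "population_structure"), N >= 2, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  labels <- names(structure$strata)
  n_J <- if (random_membership)
    as.integer(stats::rmultinom(1, N, structure$strata))
  else largest_remainder(N, as.numeric(structure$strata))
  mu <- rep_len(mu, length(labels))
  if (scenario == "umbrella" &&
      any(lengths(structure$sets) != 1L))
    stop("umbrella scenario requires disjoint singleton strata")

  rows <- list()
  for (s in seq_along(labels)) {
    n <- n_J[s]
    if (n == 0L) next
    arms_s <- switch(scenario,
      umbrella = c(paste0("T", structure$sets[[s]][1]), "C"),
      unequal_treatments = if (length(structure$sets[[s]]) > 1L)
        c(paste0("T", structure$sets[[s]]), "C")
      else c(paste0("T", structure$sets[[s]][1]), "C"),
      equal_treatments = c("T1", "C"))
    counts <- .allocate_arms(n, arms_s)
    arm <- rep(names(counts), counts)
    eff <- numeric(length(arm))
    tr <- arm != "C"
    eff[tr] <- effects[as.integer(sub("^T", "", arm[tr]))]
    rows[[s]] <- data.frame(stratum = labels[s], arm = arm,
                            outcome = stats::rnorm(n, mu[s] + eff, sigma),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- data.frame(subject_id = seq_len(nrow(out)), out, row.names = NULL)
  out
}

#' Two-population z-statistics from subject-level data
#'
#' Computes the shared-control z-statistics of the two-population single
#' trial, with the residual standard deviation \code{sigma} treated as
#' known.  Under \code{"unequal_treatments"} the population means are
#' estimated by prevalence-weighted sums of strata means (weights
#' \eqn{\pi_{\{i\}}/\pi_i} and \eqn{\pi_{\{1,2\}}/\pi_i}); under
#' \code{"equal_treatments"} by pooled means over each population.  This is
#' the simulation counterpart of the closed-form correlations in
#' [corr_two_pop_unequal_treatments()].
#'
#' @param data data frame from [simulate_trial()].
#' @param structure the [population_structure()] used for the weights.
#' @param scenario \code{"unequal_treatments"} or \code{"equal_treatments"}.
#' @param sigma known outcome standard deviation.
#' @return numeric vector \code{c(z1, z2)}.
#' @export
fit_two_pop_statistics <- function(data, structure,
                                   scenario = c("unequal_treatments",
                                                "equal_treatments"),
                                   sigma = 1) {
  scenario <- match.arg(scenario)
  pi_J <- structure$strata
  grp <- function(stratum, arm) data$outcome[data$stratum == stratum & data$arm == arm]
  z <- numeric(2)
  for (i in 1:2) {
    comp <- as.character(i); int <- "1+2"
    ti <- if (scenario == "equal_treatments") "T1" else paste0("T", i)
    if (scenario == "unequal_treatments") {
      a <- pi_J[[comp]] / (pi_J[[comp]] + pi_J[[int]])
      b <- 1 - a
      est <- numeric(2); va <- numeric(2)
      for (g in 1:2) {   # 1 = treatment, 2 = control
        arm <- if (g == 1) ti else "C"
        yc <- grp(comp, arm); yi <- grp(int, arm)
        est[g] <- a * mean(yc) + b * mean(yi)
        va[g] <- a^2 / length(yc) + b^2 / length(yi)
      }
      z[i] <- (est[1] - est[2]) / (sigma * sqrt(sum(va)))
    } else {
      yT <- c(grp(comp, ti), grp(int, ti))
      yC <- c(grp(comp, "C"), grp(int, "C"))
      z[i] <- (mean(yT) - mean(yC)) / (sigma * sqrt(1 / length(yT) + 1 / length(yC)))
    }
  }
  z
}
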