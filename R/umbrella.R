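## Umbrella-trial subset-selection procedure.
##
## l disjoint biomarker strata S_1..S_l, each with its own experimental
## treatment against a shared control; for every non-empty S subset of
## {1..l} the pooled sub-strategy hypothesis H_S: theta_S <= 0 is tested
## with a least-squares t-statistic T_S from the cell-means linear model
## Y_ij = mu_i + theta_i X_ij + eps_ij.  The statistic with the largest
## value determines the selected subset when it clears the critical value.

#' Umbrella trial design
#'
#' @param l number of disjoint strata (at most 12; the procedure enumerates
#'   all \eqn{2^l - 1} subset hypotheses).
#' @param N total sample size; must exceed \eqn{2l}.
#' @param prevalences stratum prevalences \eqn{\pi_i} (default equal);
#'   stratum sample sizes are \eqn{N \pi_i} by largest-remainder rounding,
#'   split 1:1 between experimental arm and control (treatment rounded down
#'   on odd counts).
#' @param sigma residual standard deviation of the outcome.
#' @param alpha one-sided level.
#' @param effects per-stratum treatment effects \eqn{\theta_i}; if omitted,
#'   built by [effect_grid()] from \code{q}, \code{tau},
#'   \code{theta_overall}.
#' @param q fraction of true null strata (\eqn{ql} integral).
#' @param tau relative half-range of the positive effects, in \eqn{[0, 1)}.
#' @param theta_overall prevalence-weighted mean of the positive effects.
#' @param mu per-stratum intercepts (default 0).
#' @return an object of class \code{"umbrella_design"}.
#' @examples
#' umbrella_design(l = 2, N = 1056, q = 0, tau = 0, theta_overall = 0.1)
#' @export
umbrella_design <- function(l, N = 1056, prevalences = rep(1 / l, l), sigma = 1,
                            alpha = 0.025, effects = NULL, q = NULL, tau = NULL,
                            theta_overall = NULL, mu = rep(0, l)) {
  stopifnot(l >= 1, l <= 12, N > 2 * l, sigma > 0, alpha > 0, alpha < 1,
            length(prevalences) == l, all(prevalences > 0),
            abs(sum(prevalences) - 1) < 1e-9, length(mu) == l)
  if (is.null(effects)) {
    if (is.null(q)) {
      effects <- rep(0, l)
    } else {
      if (max(abs(prevalences - 1 / l)) > 1e-9)
        stop("the (q, tau, theta_overall) grid assumes equal prevalences")
      effects <- effect_grid(l, q, tau %||% 0, theta_overall %||% 0.1)
    }
  }
  stopifnot(length(effects) == l)
  n_i <- largest_remainder(N, prevalences)
  structure(list(l = l, N = N, prevalences = prevalences, sigma = sigma,
                 alpha = alpha, effects = effects, mu = mu,
                 n_stratum = n_i, n_treat = floor(n_i / 2),
                 n_control = n_i - floor(n_i / 2)),
            class = "umbrella_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.umbrella_design <- function(x, ...) {
  cat(sprintf("Umbrella design: l = %d strata, N = %d, sigma = %g, alpha = %g\n",
              x$l, x$N, x$sigma, x$alpha))
  cat("  prevalences:", paste(sprintf("%.4g", x$prevalences), collapse = ", "), "\n")
  cat("  effects:    ", paste(sprintf("%.4g", x$effects), collapse = ", "), "\n")
  cat("  per-stratum n (treat/control):",
      paste(sprintf("%d (%d/%d)", x$n_stratum, x$n_treat, x$n_control),
            collapse = ", "), "\n")
  invisible(x)
}

#' Effect vector from (q, tau, theta_overall)
#'
#' Builds the unique vector of \eqn{l} stratum effects (equal prevalences)
#' with a fraction \eqn{q} of exact nulls and the positive effects on an
#' equidistant grid from \eqn{\theta_{\min} = \theta_{overall}(1-\tau)} to
#' \eqn{\theta_{\max} = \theta_{overall}(1+\tau)}, so that their mean is
#' \eqn{\theta_{overall}} and their relative half-range
#' \eqn{(\theta_{\max}-\theta_{\min})/(\theta_{\max}+\theta_{\min})} is
#' \eqn{\tau}.  Nulls come first.
#'
#' @param l number of strata.
#' @param q fraction of true nulls; \eqn{ql} must be an integer.
#' @param tau relative half-range in \eqn{[0, 1)}; must be 0 when at most
#'   one effect is positive.
#' @param theta_overall mean positive effect (outcome units).
#' @return numeric effect vector of length \code{l}.
#' @examples
#' effect_grid(2, q = 0, tau = 0.8, theta_overall = 0.1)  # 0.02, 0.18
#' @export
effect_grid <- function(l, q, tau, theta_overall) {
  stopifnot(l >= 1, q >= 0, q <= 1, tau >= 0, tau < 1, theta_overall >= 0)
  l0 <- q * l
  if (abs(l0 - round(l0)) > 1e-8) stop("q * l must be an integer")
  l0 <- as.integer(round(l0))
  lp <- l - l0
  if (lp <= 1 && tau != 0)
    stop("tau = 0 is the only possible value with at most one positive effect")
  pos <- if (lp == 0) numeric(0)
         else if (lp == 1) theta_overall
         else seq(theta_overall * (1 - tau), theta_overall * (1 + tau),
                  length.out = lp)
  c(rep(0, l0), pos)
}

#' Joint null t-distribution of the umbrella subset statistics
#'
#' Under the global null and homogeneous residual variance, the \eqn{2^l-1}
#' statistics \eqn{T_S} follow a joint t-distribution with \eqn{N - 2l}
#' degrees of freedom.  The correlation matrix follows from the contrast
#' vectors of \eqn{\theta_S = \sum_{i \in S} (\pi_i/\pi_S)\,\theta_i} and
#' the per-stratum estimator variances \eqn{1/n_{i,T} + 1/n_{i,C}} (the
#' \eqn{\hat\theta_i} are independent across strata).  Subsets are
#' enumerated by cardinality, then lexicographically.
#'
#' @param design an [umbrella_design()].
#' @return a [joint_null_model()] (class also \code{"umbrella_null_model"})
#'   with extra components \code{subsets}, \code{contrast} (weight matrix
#'   \eqn{W}), \code{var_scale} (\eqn{\mathrm{Var}(\hat\theta_S)/\sigma^2})
#'   and \code{design}.
#' @export
umbrella_null_model <- function(design) {
  stopifnot(inherits(design, "umbrella_design"))
  l <- design$l
  subsets <- .all_subsets(l)
  labels <- format_stratum(subsets)
  v_i <- 1 / design$n_treat + 1 / design$n_control   # Var(theta_hat_i) / sigma^2
  W <- t(vapply(subsets, function(s) {
    w <- numeric(l)
    w[s] <- design$prevalences[s] / sum(design$prevalences[s])
    w
  }, numeric(l)))
  Cov <- W %*% (v_i * t(W))
  R <- stats::cov2cor(Cov)
  model <- joint_null_model(R, family = "student_t", df = design$N - 2 * l,
                            labels = labels, affects = subsets)
  model$subsets <- subsets
  model$contrast <- W
  model$var_scale <- diag(Cov)
  model$design <- design
  class(model) <- c("umbrella_null_model", class(model))
  model
}

#' Subset t-statistics from subject-level umbrella-trial data
#'
#' Least-squares fit of the cell-means model (stratum intercepts plus
#' stratum treatment effects, \eqn{2l} parameters): per-stratum arm means
#' give \eqn{\hat\theta_i}, the pooled within-group variance with
#' \eqn{N - 2l} degrees of freedom gives \eqn{\hat\sigma^2}, and
#' \eqn{T_S = \hat\theta_S / \mathrm{SE}(\hat\theta_S)} with
#' \eqn{\hat\theta_S = \sum_{i \in S} (\pi_i/\pi_S) \hat\theta_i}.
#'
#' @param data data frame with columns \code{stratum} (labels
#'   \code{"1"}..\code{"l"}), \code{arm} (\code{"C"} for control, anything
#'   else experimental) and \code{outcome}, e.g. from [simulate_trial()].
#' @param design an [umbrella_design()].
#' @return a list with \code{statistics} (named \eqn{T_S} vector in
#'   canonical subset order), \code{theta_hat}, \code{sigma_hat}, \code{df}.
#' @export
fit_subset_statistics <- function(data, design) {
  stopifnot(all(c("stratum", "arm", "outcome") %in% names(data)))
  l <- design$l
  stratum <- as.integer(as.character(data$stratum))
  if (anyNA(stratum) || any(stratum < 1L) || any(stratum > l))
    stop("stratum labels must be 1..l")
  treated <- !(data$arm %in% c("C", "control"))
  N <- nrow(data)
  if (N <= 2 * l) stop("N must exceed 2l")
  theta_hat <- numeric(l)
  ss <- 0
  for (i in seq_len(l)) {
    yT <- data$outcome[stratum == i & treated]
    yC <- data$outcome[stratum == i & !treated]
    if (length(yT) == 0L || length(yC) == 0L)
      stop("stratum ", i, " lacks an arm")
    theta_hat[i] <- mean(yT) - mean(yC)
    ss <- ss + sum((yT - mean(yT))^2) + sum((yC - mean(yC))^2)
  }
  if (ss <= 0) stop("zero residual variance: subset statistics are undefined")
  df <- N - 2 * l
  s2 <- ss / df
  nT <- vapply(seq_len(l), function(i) sum(stratum == i & treated), numeric(1))
  nC <- vapply(seq_len(l), function(i) sum(stratum == i & !treated), numeric(1))
  v_i <- 1 / nT + 1 / nC
  subsets <- .all_subsets(l)
  W <- t(vapply(subsets, function(s) {
    w <- numeric(l)
    w[s] <- design$prevalences[s] / sum(design$prevalences[s])
    w
  }, numeric(l)))
  est <- as.numeric(W %*% theta_hat)
  se <- sqrt(s2 * as.numeric(W^2 %*% v_i))
  list(statistics = stats::setNames(est / se, format_stratum(subsets)),
       theta_hat = theta_hat, sigma_hat = sqrt(s2), df = df)
}

#' Subset selection by the max-statistic rule
#'
#' Selects \eqn{S^* = \arg\max_S T_S} when \eqn{\max_S T_S > c}, otherwise
#' the empty set.  Exact ties are broken by smallest cardinality, then
#' lexicographic order of the subset labels.
#'
#' @param statistics named vector of subset statistics (labels in the
#'   \code{"1+2"} dialect).
#' @param c critical value.
#' @return a list with \code{selected} (integer vector, possibly empty),
#'   \code{label} (\code{NA} if none), \code{statistic}, \code{threshold}.
#' @export
select_subset <- function(statistics, c) {
  stopifnot(length(statistics) >= 1L, !is.null(names(statistics)))
  sets <- parse_stratum(names(statistics))
  ord <- .stratum_order(sets)
  statistics <- statistics[ord]; sets <- sets[ord]
  best <- which.max(statistics)   # first maximum in canonical order
  if (statistics[best] > c)
    list(selected = sets[[best]], label = names(statistics)[best],
         statistic = as.numeric(statistics[best]), threshold = c)
  else
    list(selected = integer(0), label = NA_character_,
         statistic = as.numeric(max(statistics)), threshold = c)
}

#' PWER- and FWER-controlling thresholds for an umbrella design
#'
#' The FWER threshold is the upper \eqn{\alpha}-quantile of
#' \eqn{\max_S T_S} under the global null.  The PWER threshold solves
#' \deqn{\mathrm{PWER}_0 = \sum_{i=1}^l \pi_i \,
#'   P_0\!\left(\bigcup_{S \ni i} \{T_S \ge c_P^*\}\right) = \alpha,}
#' which is strictly smaller whenever some subsets are disjoint.
#'
#' @param design an [umbrella_design()].
#' @param model optional pre-computed [umbrella_null_model()].
#' @return list with \code{c_pwer}, \code{c_fwer} and the \code{model}.
#' @export
umbrella_critical_values <- function(design, model = umbrella_null_model(design)) {
  strata <- population_structure(stats::setNames(design$prevalences,
                                                 as.character(seq_len(design$l))))
  tol <- 1e-7   # threshold precision well below any simulation resolution
  c_p <- pwer_critical_value(strata, model, alpha = design$alpha, tol = tol)$c_star
  c_f <- fwer_critical_value(model, alpha = design$alpha, tol = tol)$c_star
  list(c_pwer = c_p, c_fwer = c_f, model = model)
}

#' Simulate umbrella trials and summarize selection performance
#'
#' For each \code{(q, tau)} scenario, simulates \code{n_reps} trials from
#' the design's linear model at subject level, computes all subset
#' statistics per replicate (least squares, reduced over per-group means and
#' sums of squares), applies both the PWER- and FWER-calibrated selection
#' rules to the same replicates and reports, in percent: power (reject any
#' \eqn{H_S} with \eqn{\theta_S > 0}), the mean prevalence fractions of
#' correctly (\eqn{\pi_{S^*_+}/\pi_{S^*}}) and falsely
#' (\eqn{\pi_{S^*_0}/\pi_{S^*}}) chosen strata within the selected subset
#' (0 when nothing is selected), and the relative average effect
#' \eqn{\mathrm{RAE} = 100\,E(\sum_{i \in S^*} \pi_i \theta_i) /
#' \theta_{overall}} (reported as 0 under the global null, where
#' \eqn{\theta_{overall}} is undefined).
#'
#' @param design an [umbrella_design()]; its effects are overridden per
#'   scenario via [effect_grid()] with \code{theta_overall}.
#' @param scenarios data frame with columns \code{q} and \code{tau}.
#' @param theta_overall mean positive effect used for all scenarios.
#' @param n_reps replicates per scenario.
#' @param seed RNG seed (one stream; scenarios are simulated in order).
#' @param methods which calibrations to report.
#' @return data frame with columns \code{l}, \code{q}, \code{tau},
#'   \code{method}, \code{power}, \code{correct}, \code{false}, \code{rae},
#'   \code{mc_se_power}, \code{n_reps}.
#' @export
run_performance_study <- function(design, scenarios, theta_overall = 0.1,
                                  n_reps = 10000, seed = 1,
                                  methods = c("pwer", "fwer")) {
  stopifnot(inherits(design, "umbrella_design"),
            all(c("q", "tau") %in% names(scenarios)), n_reps >= 100)
  methods <- match.arg(methods, several.ok = TRUE)
  cv <- umbrella_critical_values(design)
  model <- cv$model
  l <- design$l
  subsets <- model$subsets
  W <- model$contrast
  v_i <- 1 / design$n_treat + 1 / design$n_control
  v_S <- as.numeric(W^2 %*% v_i)
  df <- design$N - 2 * l
  pi_i <- design$prevalences
  ## per-subset summaries for the selection measures
  frac_false0 <- function(theta) vapply(subsets, function(s)
    sum(pi_i[s][theta[s] <= 0]) / sum(pi_i[s]), numeric(1))
  eff_sum <- function(theta) vapply(subsets, function(s)
    sum(pi_i[s] * theta[s]), numeric(1))

  set.seed(seed)
  out <- list()
  for (r in seq_len(nrow(scenarios))) {
    q <- scenarios$q[r]; tau <- scenarios$tau[r]
    theta <- effect_grid(l, q, tau, theta_overall)
    ## subject-level outcomes, reduced per group across all replicates
    theta_hat <- matrix(0, n_reps, l)
    ss <- numeric(n_reps)
    for (i in seq_len(l)) {
      for (arm in c("T", "C")) {
        n_g <- if (arm == "T") design$n_treat[i] else design$n_control[i]
        mu_g <- design$mu[i] + if (arm == "T") theta[i] else 0
        X <- matrix(stats::rnorm(n_g * n_reps, mu_g, design$sigma), n_g, n_reps)
        mns <- colMeans(X)
        ss <- ss + colSums(X^2) - n_g * mns^2
        theta_hat[, i] <- theta_hat[, i] + if (arm == "T") mns else -mns
      }
    }
    s2 <- ss / df
    TS <- (theta_hat %*% t(W)) / sqrt(outer(s2, v_S))   # n_reps x (2^l - 1)
    theta_S <- as.numeric(W %*% theta)
    mx <- do.call(pmax, as.data.frame(TS))
    sel <- max.col(TS, ties.method = "first")           # canonical tie-break
    ff <- frac_false0(theta); es <- eff_sum(theta)
    for (method in methods) {
      c_star <- if (method == "pwer") cv$c_pwer else cv$c_fwer
      rej <- mx > c_star
      pw <- if (any(theta_S > 0))
        mean(rowSums(TS[, theta_S > 0, drop = FALSE] > c_star) > 0) else 0
      false_p <- mean(ifelse(rej, ff[sel], 0))
      corr_p <- mean(ifelse(rej, 1 - ff[sel], 0))
      rae <- if (theta_overall > 0 && any(theta > 0))
        100 * mean(ifelse(rej, es[sel], 0)) / theta_overall else 0
      out[[length(out) + 1L]] <- data.frame(
        l = l, q = q, tau = tau, method = toupper(method),
        power = 100 * pw, correct = 100 * corr_p, false = 100 * false_p,
        rae = rae, mc_se_power = 100 * sqrt(pw * (1 - pw) / n_reps),
        n_reps = n_reps)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "c_pwer") <- cv$c_pwer
  attr(res, "c_fwer") <- cv$c_fwer
  res
}

#' @describeIn umbrella_design \code{simulate} method: subject-level data
#'   for \code{nsim} trials (a list of data frames, or a single data frame
#'   when \code{nsim = 1}).
#' @param object,nsim,... see [stats::simulate()].
#' @export
simulate.umbrella_design <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  strata <- population_structure(stats::setNames(object$prevalences,
                                                 as.character(seq_len(object$l))))
  sims <- lapply(seq_len(nsim), function(i)
    simulate_trial(strata, scenario = "umbrella", effects = object$effects,
                   sigma = object$sigma, N = object$N, mu = object$mu))
  if (nsim == 1) sims[[1]] else sims
}
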