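#' Joint null distribution of the test statistics
#'
#' Specifies the joint distribution of the one-sided test statistics under
#' the least favourable (global null) configuration: multivariate normal, or
#' multivariate t with \code{df} degrees of freedom, with the given
#' correlation matrix.  Each statistic tests one hypothesis; the hypothesis
#' label records which populations the hypothesis concerns (a single index
#' \code{"2"}, or a union \code{"1+3"} as in umbrella subset hypotheses), so
#' that the population-wise error rate knows which rejections affect which
#' stratum.
#'
#' @param correlation correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite).  A scalar is taken as the off-diagonal correlation of a
#'   bivariate model.
#' @param family \code{"normal"} or \code{"student_t"}.
#' @param df degrees of freedom (\code{family = "student_t"} only).
#' @param labels per-statistic hypothesis labels; default \code{"1"},
#'   \code{"2"}, ... (statistic \eqn{i} tests population \eqn{i}).
#' @param affects optional list of integer vectors: the population indices
#'   each hypothesis concerns.  Defaults to the parsed labels.
#' @return an object of class \code{"joint_null_model"}.
#' @examples
#' joint_null_model(0.5)                      # bivariate normal, rho = 0.5
#' joint_null_model(diag(3), family = "student_t", df = 10)
#' @export
joint_null_model <- function(correlation, family = c("normal", "student_t"),
                             df = NULL, labels = NULL, affects = NULL) {
  family <- match.arg(family)
  if (is.numeric(correlation) && length(correlation) == 1L && !is.matrix(correlation))
    correlation <- matrix(c(1, correlation, correlation, 1), 2L, 2L)
  correlation <- as.matrix(correlation)
  k <- nrow(correlation)
  if (ncol(correlation) != k) stop("correlation must be square")
  if (max(abs(correlation - t(correlation))) > 1e-8) stop("correlation must be symmetric")
  correlation <- (correlation + t(correlation)) / 2
  if (max(abs(diag(correlation) - 1)) > 1e-8) stop("correlation must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("correlation must be positive semi-definite")
  if (family == "student_t") {
    if (is.null(df) || !is.numeric(df) || df < 1) stop("student_t requires df >= 1")
  } else df <- Inf
  if (is.null(labels)) {
    labels <- if (!is.null(colnames(correlation))) colnames(correlation)
              else as.character(seq_len(k))
  }
  stopifnot(length(labels) == k)
  if (is.null(affects)) affects <- parse_stratum(labels)
  stopifnot(length(affects) == k)
  dimnames(correlation) <- list(labels, labels)
  structure(list(k = k, family = family, df = df, correlation = correlation,
                 labels = as.character(labels), affects = affects),
            class = "joint_null_model")
}

#' @export
print.joint_null_model <- function(x, ...) {
  cat(sprintf("Joint null model: %d statistic(s), %s%s\n", x$k, x$family,
              if (x$family == "student_t") sprintf(" (df = %g)", x$df) else ""))
  print(round(x$correlation, 4))
  invisible(x)
}

## ---- deterministic multivariate normal / t lower CDF -----------------------
##
## Miwa's quadrature is fully deterministic and, at 512 grid points, accurate
## far beyond 1e-10 in the low dimensions used here.  Singular correlation
## matrices and larger problems fall back to Genz-Bretz quasi-Monte-Carlo,
## evaluated under a fixed internal seed so results are identical run to run
## ("deterministic to tolerance").
.with_fixed_seed <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(970813L)
  force(expr)
}

.mv_cdf <- function(upper, corr, df = Inf) {
  k <- length(upper)
  if (any(is.na(upper))) stop("non-finite threshold")
  if (k == 1L)
    return(if (is.finite(df)) stats::pt(upper, df = df) else stats::pnorm(upper))
  ev_min <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (!is.finite(df)) {
    if (ev_min > 1e-8 && k <= 6L) {
      p <- mvtnorm::pmvnorm(upper = upper, corr = corr,
                            algorithm = mvtnorm::Miwa(steps = 512))
    } else {
      p <- .with_fixed_seed(
        mvtnorm::pmvnorm(upper = upper, corr = corr,
                         algorithm = mvtnorm::GenzBretz(abseps = 1e-9, maxpts = 1e6)))
    }
  } else {
    abseps <- if (k <= 4L) 1e-8 else 1e-6
    maxpts <- if (k <= 4L) 5e6 else 1e6
    p <- .with_fixed_seed(
      mvtnorm::pmvt(upper = upper, corr = corr, df = as.integer(round(df)),
                    algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = maxpts)))
  }
  min(max(as.numeric(p), 0), 1)
}

## P(any Z_j >= bound_j) for the sub-vector idx
.joint_exceed <- function(model, idx, bounds) {
  if (length(idx) == 0L) return(0)
  if (any(bounds == Inf) && all(bounds == Inf)) return(0)
  1 - .mv_cdf(bounds, model$correlation[idx, idx, drop = FALSE], model$df)
}

#' Joint upper-tail probability
#'
#' Computes \eqn{P(\max_{j \in \mathrm{subset}} Z_j \ge c)} under the joint
#' null model, i.e. one minus the multivariate CDF of the sub-vector at
#' \eqn{(c, \dots, c)}.
#'
#' @param model a [joint_null_model()].
#' @param subset indices (or labels) of the statistics; default all.
#' @param c threshold (finite or \code{Inf}).
#' @return a probability.
#' @export
joint_tail <- function(model, subset = NULL, c) {
  stopifnot(inherits(model, "joint_null_model"), length(c) == 1L)
  if (is.null(subset)) subset <- seq_len(model$k)
  if (is.character(subset)) subset <- match(subset, model$labels)
  if (length(subset) == 0L || anyNA(subset)) stop("empty or unknown subset")
  if (is.infinite(c) && c > 0) return(0)
  .joint_exceed(model, subset, rep(c, length(subset)))
}

## marginal (1 - p)-quantile of the model's null marginals
.marginal_quantile <- function(model, p) {
  if (is.finite(model$df)) stats::qt(p, df = model$df) else stats::qnorm(p)
}

## ---- design-scenario correlations -----------------------------------------

#' Correlation of the two z-statistics in the shared-control scenarios
#'
#' Two overlapping populations of equal size (\eqn{\pi_{\{1\}} = \pi_{\{2\}}})
#' are tested against a common control in one trial.  With *different*
#' treatments per population (1:1 randomization in the complements, 1:1:1 in
#' the intersection, population means estimated by prevalence-weighted sums
#' of strata means) the statistics correlate through the shared control only:
#' \deqn{\mathrm{Corr}(Z_1, Z_2) = \frac{3}{2}\,
#'   \frac{\pi_{\{1,2\}}}{1 + 2\pi_{\{1,2\}}}.}
#' With the *same* treatment in both populations (1:1 randomization in every
#' stratum, pooled means) the intersection subjects are shared in both arms:
#' \deqn{\mathrm{Corr}(Z_1, Z_2) = \frac{2 \pi_{\{1,2\}}}{1 + \pi_{\{1,2\}}},}
#' which dominates the unequal-treatment correlation for every overlap.
#'
#' @param pi12 prevalence of the intersection stratum, in \eqn{[0, 1]}.
#' @return the correlation.
#' @export
corr_two_pop_unequal_treatments <- function(pi12) {
  stopifnot(is.numeric(pi12), pi12 >= 0, pi12 <= 1)
  1.5 * pi12 / (1 + 2 * pi12)
}

#' @rdname corr_two_pop_unequal_treatments
#' @export
corr_two_pop_equal_treatments <- function(pi12) {
  stopifnot(is.numeric(pi12), pi12 >= 0, pi12 <= 1)
  2 * pi12 / (1 + pi12)
}

#' Correlation matrix for nested populations under a single treatment
#'
#' For a chain \eqn{P_1 \supset P_2 \supset \dots \supset P_m} tested with
#' one treatment, balanced arms in each stratum and sample sizes proportional
#' to the prevalences, the pooled z-statistics satisfy
#' \eqn{\mathrm{Corr}(Z_i, Z_j) = \sqrt{\pi_j / \pi_i}} for \eqn{j > i},
#' where \eqn{\pi_i} is the population prevalence.
#'
#' @param structure a [population_structure()] whose strata are the chain
#'   prefixes \code{"1"}, \code{"1+2"}, ..., \code{"1+2+...+m"}.
#' @return an \eqn{m \times m} correlation matrix.
#' @export
corr_nested_single_treatment <- function(structure) {
  stopifnot(inherits(structure, "population_structure"))
  ok <- vapply(structure$sets, function(s) identical(s, seq_len(length(s))), logical(1))
  if (!all(ok))
    stop("structure is not a nested chain: every stratum must be a prefix {1..i}")
  m <- structure$m
  pii <- structure$pop_prevalence
  R <- diag(m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (j > i)
    R[i, j] <- R[j, i] <- sqrt(pii[j] / pii[i])
  R
}

#' Build the joint null model for a named two-population scenario
#'
#' @param pi12 intersection prevalence.
#' @param scenario \code{"independent"} (two independent samples),
#'   \code{"unequal_treatments"} or \code{"equal_treatments"} (single trial,
#'   shared control; see [corr_two_pop_unequal_treatments()]).
#' @return a bivariate normal [joint_null_model()].
#' @export
two_pop_model <- function(pi12,
                          scenario = c("independent", "unequal_treatments",
                                       "equal_treatments")) {
  scenario <- match.arg(scenario)
  rho <- switch(scenario,
                independent = 0,
                unequal_treatments = corr_two_pop_unequal_treatments(pi12),
                equal_treatments = corr_two_pop_equal_treatments(pi12))
  joint_null_model(rho, labels = c("1", "2"))
}

#' @rdname corr_nested_single_treatment
#' @return [nested_model()] wraps the matrix in a [joint_null_model()].
#' @export
nested_model <- function(structure) {
  joint_null_model(corr_nested_single_treatment(structure),
                   labels = as.character(seq_len(structure$m)))
}
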