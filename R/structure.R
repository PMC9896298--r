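#' Overlapping-population structure
#'
#' Represents the partition of an overall patient population into disjoint
#' strata indexed by non-empty subsets of the \eqn{m} target populations
#' \eqn{P_1, \dots, P_m}.  A patient in stratum \eqn{P_J} belongs to exactly
#' the populations \eqn{P_i}, \eqn{i \in J}.  Each stratum carries its
#' relative prevalence \eqn{\pi_J}; the prevalences sum to 1.
#'
#' Strata with zero prevalence contribute nothing to the population-wise
#' error rate and are dropped with a warning, unless a prevalence floor
#' \code{min_prevalence} is given, in which case every listed stratum is
#' raised to at least the floor and the vector renormalized (mass is removed
#' proportionally from the unfloored strata).
#'
#' @param prevalences named numeric vector of stratum prevalences; names are
#'   stratum labels in the \code{"1+2"} dialect (see [parse_stratum()]).
#'   Alternatively a data frame with columns \code{stratum} and
#'   \code{prevalence}.
#' @param min_prevalence optional prevalence floor \eqn{\pi_{\min}} in
#'   \eqn{[0, 1)}; applied before renormalization.
#' @return an object of class \code{"population_structure"} with components
#'   \describe{
#'     \item{m}{number of populations (largest index appearing in a label),}
#'     \item{strata}{named prevalence vector in canonical order (by stratum
#'       cardinality, then lexicographically),}
#'     \item{sets}{the parsed index subsets,}
#'     \item{pop_prevalence}{derived population prevalences
#'       \eqn{\pi_i = \sum_{J \ni i} \pi_J}.}
#'   }
#' @examples
#' population_structure(c("1" = 0.4, "2" = 0.4, "1+2" = 0.2))
#' @export
population_structure <- function(prevalences, min_prevalence = NULL) {
  if (is.data.frame(prevalences)) {
    stopifnot(all(c("stratum", "prevalence") %in% names(prevalences)))
    prevalences <- stats::setNames(as.numeric(prevalences$prevalence),
                                   as.character(prevalences$stratum))
  }
  if (length(prevalences) == 0L)
    stop("at least one stratum is required")
  if (is.null(names(prevalences)) || any(is.na(names(prevalences))))
    stop("prevalences must be named by stratum labels (\"1\", \"1+2\", ...)")
  sets <- parse_stratum(names(prevalences))
  labels <- format_stratum(sets)
  if (anyDuplicated(labels))
    stop("duplicate stratum: ", paste(labels[duplicated(labels)], collapse = ", "))
  pi_J <- as.numeric(prevalences)
  if (anyNA(pi_J) || any(pi_J < 0))
    stop("prevalences must be non-negative")
  if (abs(sum(pi_J) - 1) > 1e-6)
    stop(sprintf("prevalences must sum to 1 (got %.8f)", sum(pi_J)))

  if (!is.null(min_prevalence)) {
    stopifnot(is.numeric(min_prevalence), length(min_prevalence) == 1L,
              min_prevalence >= 0, min_prevalence < 1)
    low <- pi_J < min_prevalence
    if (any(low)) {
      if (min_prevalence * sum(low) >= 1)
        stop("min_prevalence too large for the number of strata")
      pi_J[low] <- min_prevalence
      ## take the added mass proportionally from the unfloored strata
      pi_J[!low] <- pi_J[!low] * (1 - sum(pi_J[low])) / sum(pi_J[!low])
    }
  } else if (any(pi_J == 0)) {
    drop <- pi_J == 0
    warning("dropping zero-prevalence strata: ", paste(labels[drop], collapse = ", "))
    sets <- sets[!drop]
    labels <- labels[!drop]
    pi_J <- pi_J[!drop]
  }
  pi_J <- pi_J / sum(pi_J)  # guard rounding; sum is 1 within 1e-9 already

  ord <- .stratum_order(sets)
  sets <- sets[ord]; labels <- labels[ord]; pi_J <- pi_J[ord]
  m <- max(unlist(sets))
  pop_prev <- vapply(seq_len(m), function(i)
    sum(pi_J[vapply(sets, function(s) i %in% s, logical(1))]), numeric(1))

  stopifnot(abs(sum(pi_J) - 1) < 1e-9, all(pop_prev >= 0), all(pop_prev <= 1 + 1e-12))
  structure(list(m = m, strata = stats::setNames(pi_J, labels), sets = sets,
                 pop_prevalence = pop_prev, min_prevalence = min_prevalence),
            class = "population_structure")
}

#' @export
print.population_structure <- function(x, ...) {
  cat(sprintf("Population structure: %d populations, %d strata\n", x$m,
              length(x$strata)))
  print(round(x$strata, 6))
  cat("Population prevalences pi_i:",
      paste(sprintf("%.4g", x$pop_prevalence), collapse = ", "), "\n")
  invisible(x)
}

#' Maximum-likelihood prevalence estimates from stratum counts
#'
#' The MLE under the multinomial distribution of the stratum counts is
#' \eqn{\hat\pi_J = n_J / N}.  An optional prevalence floor is applied after
#' estimation (see [population_structure()]).
#'
#' @param counts named non-negative integer vector of stratum counts
#'   (labels as in [parse_stratum()]), or a data frame with columns
#'   \code{stratum} and \code{count}.
#' @param min_prevalence optional floor passed to [population_structure()].
#' @return a [population_structure()].
#' @examples
#' mle_prevalences(c("1" = 30, "2" = 30, "1+2" = 40))
#' @export
mle_prevalences <- function(counts, min_prevalence = NULL) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("stratum", "count") %in% names(counts)))
    counts <- stats::setNames(as.numeric(counts$count), as.character(counts$stratum))
  }
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative")
  N <- sum(counts)
  if (N < 1) stop("all counts are zero; at least one subject is required")
  population_structure(counts / N, min_prevalence = min_prevalence)
}

#' Read / write prevalence and count tables
#'
#' CSV interface for prevalence tables (header \code{stratum,prevalence}) and
#' stratum count tables (header \code{stratum,count}), one row per non-empty
#' stratum with labels in the \code{"1+2"} dialect.
#'
#' @param file path to a CSV file.
#' @param min_prevalence optional floor, see [population_structure()].
#' @return [read_prevalences()] returns a [population_structure()];
#'   [read_stratum_counts()] a named count vector.
#' @export
read_prevalences <- function(file, min_prevalence = NULL) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  population_structure(tab, min_prevalence = min_prevalence)
}

#' @rdname read_prevalences
#' @export
read_stratum_counts <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("stratum", "count") %in% names(tab)))
  stats::setNames(as.numeric(tab$count), as.character(tab$stratum))
}

#' @rdname read_prevalences
#' @param structure a [population_structure()].
#' @export
write_prevalences <- function(structure, file) {
  stopifnot(inherits(structure, "population_structure"))
  utils::write.csv(data.frame(stratum = names(structure$strata),
                              prevalence = as.numeric(structure$strata)),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
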