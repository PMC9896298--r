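#' Parse a stratum label
#'
#' Stratum labels use the \code{"1+2"} dialect: 1-based population indices
#' joined by \code{"+"}. \code{parse_stratum("1+2")} returns the index set
#' \code{c(1L, 2L)}.
#'
#' @param x character vector of stratum labels.
#' @return a list of sorted integer vectors (one per label).
#' @seealso [format_stratum()]
#' @export
parse_stratum <- function(x) {
  lapply(strsplit(as.character(x), "+", fixed = TRUE), function(parts) {
    parts <- trimws(parts)
    if (length(parts) == 0L || any(parts == ""))
      stop("empty stratum label: a stratum must be a non-empty index subset")
    idx <- suppressWarnings(as.integer(parts))
    if (anyNA(idx) || any(idx < 1L))
      stop("invalid stratum label: indices must be positive integers, got ",
           paste(parts, collapse = "+"))
    if (anyDuplicated(idx))
      stop("invalid stratum label: repeated index in ", paste(parts, collapse = "+"))
    sort(idx)
  })
}

#' Format an index set as a stratum label
#'
#' @param j integer vector of 1-based population indices (or a list of them).
#' @return character label(s) in the \code{"1+2"} dialect.
#' @export
format_stratum <- function(j) {
  if (is.list(j)) return(vapply(j, format_stratum, character(1)))
  paste(sort(as.integer(j)), collapse = "+")
}

## canonical order: by cardinality, then lexicographically on the index vector
.stratum_order <- function(sets) {
  key <- vapply(sets, function(s) paste(sprintf("%03d", s), collapse = ","), character(1))
  order(lengths(sets), key)
}

## all non-empty subsets of 1..l in canonical order
.all_subsets <- function(l) {
  stopifnot(l >= 1L)
  sets <- unlist(lapply(seq_len(l), function(k) utils::combn(l, k, simplify = FALSE)),
                 recursive = FALSE)
  sets[.stratum_order(sets)]
}
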