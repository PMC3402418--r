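#' Damerau-Levenshtein distance between two symbol strings
#'
#' Minimal number of single-symbol insertions, deletions, substitutions and
#' adjacent transpositions converting `a` into `b`, in the restricted
#' (optimal string alignment) regime where no substring is edited twice.
#' This is the distance underlying the pattern affinity score: each edit
#' operation is treated as an elementary deviation from a pattern, so the
#' distance counts how strongly a produced stretch departs from it.
#'
#' Symbols are compared by equality only; inputs may be character or numeric
#' vectors (one element per symbol) and may be empty.
#'
#' @param a,b Symbol vectors.
#' @return Non-negative integer distance.
#' @examples
#' dl_distance(c(2, 1, 9, 6), c(2, 1, 6))  # one deletion
#' dl_distance(c(1, 2), c(2, 1))           # one adjacent transposition
#' @seealso [oracle_distance()] for the exhaustive test oracle,
#'   [anchored_distance()] for the pattern-vs-position variant.
#' @export
dl_distance <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  syms <- unique(c(a, b))
  cpp_osa(match(a, syms) - 1L, match(b, syms) - 1L)
}

#' Exhaustive reference implementation of the edit distance
#'
#' Memoized recursion straight from the four-operation definition
#' (insertion, deletion, substitution, adjacent transposition; restricted
#' regime). Exists solely as an independent oracle for testing the dynamic
#' programming implementation and is deliberately limited to short strings.
#'
#' @param a,b Symbol vectors of length at most 6.
#' @return Non-negative integer distance.
#' @export
oracle_distance <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) > 6 || length(b) > 6) {
    stop("oracle_distance is an exhaustive test oracle limited to strings of length <= 6",
         call. = FALSE)
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (a[i] == b[j]) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L, rec(i - 1L, j - 1L) + cost)
    if (i >= 2L && j >= 2L && a[i] == b[j - 1L] && a[i - 1L] == b[j]) {
      v <- min(v, rec(i - 2L, j - 2L) + 1L)
    }
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

#' Anchored distance of a pattern at a sequence position
#'
#' Semi-global comparison used to score a pattern "at" a position: the
#' distance is the minimum Damerau-Levenshtein distance between the pattern
#' and any window of the sequence starting at position `i` (free end,
#' including the empty window, whose cost is the pattern length `n`). Near
#' the sequence end the minimum runs over the available suffixes, so
#' truncation is handled naturally. The default free-end reading lets a
#' single insertion or deletion inside an otherwise intact pattern cost
#' exactly 1; the `"fixed"` alternative compares against the length-`n`
#' window only and is provided for sensitivity analysis.
#'
#' @param pattern Symbol vector (the pattern `m`, length `n >= 1`).
#' @param z Symbol vector or [rngt_trial()] (the sequence).
#' @param i Start position, 1-based, `1 <= i <= length(z)`.
#' @param window `"free"` (default) or `"fixed"` — see Details.
#' @return Non-negative integer distance, at most `n`.
#' @examples
#' anchored_distance(c(1, 2, 3), c(1, 2, 3, 9, 9), 1)  # exact window: 0
#' anchored_distance(c(1, 2, 3), c(9, 1, 2, 3, 9), 1)  # delete leading 9: 1
#' @export
anchored_distance <- function(pattern, z, i, window = c("free", "fixed")) {
  prof <- anchored_profile(pattern, z, window)
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > length(prof)) {
    stop(sprintf("start position i must lie in 1..%d", length(prof)), call. = FALSE)
  }
  prof[[as.integer(i)]]
}

#' Anchored distances at every start position
#'
#' Vectorized form of [anchored_distance()]: element `i` is the anchored
#' distance of the pattern at start position `i`. This profile is the raw
#' material of the affinity score.
#'
#' @inheritParams anchored_distance
#' @return Integer vector of length `length(z)`.
#' @export
anchored_profile <- function(pattern, z, window = c("free", "fixed")) {
  if (inherits(z, "rngt_trial")) z <- z$sequence
  pattern <- as.character(pattern)
  z <- as.character(z)
  if (length(pattern) < 1) stop("pattern must have length >= 1", call. = FALSE)
  if (length(z) < 1) stop("sequence must have length >= 1", call. = FALSE)
  syms <- unique(c(pattern, z))
  cpp_anchored_profile(match(pattern, syms) - 1L, match(z, syms) - 1L,
                       window_fixed(window))
}
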