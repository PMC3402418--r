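#' Pattern affinity score on a sequence
#'
#' Measures how strongly a pattern `m` (an n-tuple of alphabet symbols) and
#' its close variants are represented in a sequence `z`. At every start
#' position `i = 1..l` the anchored edit distance `d_i` of the pattern is
#' computed (see [anchored_distance()]), mapped through a monotone-decreasing
#' affinity transform `a(d)`, summed and divided by the sequence length:
#'
#' \deqn{s(m, z) = \frac{1}{l} \sum_{i=1}^{l} a(d_i)}
#'
#' The default transform is `a(d) = 1/(1 + d)`, bounded in (0, 1], so a
#' perfect match contributes 1 and each additional edit operation discounts
#' the contribution; a plain reciprocal would be undefined at the perfect
#' match `d = 0`. The alternative `"invcap"` transform uses `1/d` with
#' `a(0) = cap` for sensitivity checks.
#'
#' @param pattern Symbol vector, `1 <= n <= length(z)`.
#' @param z Symbol vector or [rngt_trial()].
#' @param affinity `"inv1p"` (default, `1/(1+d)`) or `"invcap"` (`1/d`,
#'   `a(0) = cap`).
#' @param cap Value of `a(0)` under `"invcap"`; ignored otherwise.
#' @param window Passed to [anchored_profile()].
#' @param per_position If `TRUE`, retain the per-start-position distances and
#'   affinities.
#' @return An object of class `rngt_score`: list with `value` (the score,
#'   in (0, 1] under the default transform) and, if requested,
#'   `per_position` (data.frame with `position`, `distance`, `affinity`).
#' @examples
#' # a dominant pattern scores high on the sequence that carries it
#' z <- rep(c(2, 1, 9, 6), 10)
#' pattern_score(c(2, 1, 9, 6), z)$value
#' @export
pattern_score <- function(pattern, z, affinity = c("inv1p", "invcap"), cap = 2,
                          window = c("free", "fixed"), per_position = FALSE) {
  if (inherits(z, "rngt_trial")) z <- z$sequence
  pattern <- as.character(pattern)
  z <- as.character(z)
  n <- length(pattern)
  l <- length(z)
  if (n > l) {
    stop(sprintf("pattern length n = %d exceeds sequence length l = %d", n, l),
         call. = FALSE)
  }
  prof <- anchored_profile(pattern, z, window)
  avals <- affinity_transform(prof, match.arg(affinity), cap)
  out <- list(value = sum(avals) / l, n = n, l = l)
  if (per_position) {
    out$per_position <- data.frame(position = seq_len(l), distance = prof,
                                   affinity = avals)
  }
  structure(out, class = "rngt_score")
}

#' @export
print.rngt_score <- function(x, ...) {
  cat(sprintf("<rngt_score> s = %.6f (pattern n = %d on sequence l = %d)\n",
              x$value, x$n, x$l))
  invisible(x)
}
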