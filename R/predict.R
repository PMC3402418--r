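#' Candidate scores for the next item given a history
#'
#' For each alphabet symbol `j`, scores the pattern formed by the recent
#' history extended by `j` against one or more source sequences:
#' `q(j) = s((history, j), x)`, averaged over sources. The best estimate for
#' the next item is the symbol maximizing `q(j)`. With an empty history
#' (`h = 0`) this reduces to single-symbol frequency scoring, i.e. a
#' majority classifier.
#'
#' @param history Symbol vector of length `h >= 0` (most recent symbol last).
#' @param sources An [rngt_trial()], [rngt_cohort()], symbol vector, or list
#'   of these; every source must be at least `h + 1` symbols long.
#' @param alphabet Alphabet defining the candidate set; defaults to the first
#'   source trial's alphabet, else digits 1-9.
#' @param affinity,cap,window Passed to the affinity score; see
#'   [pattern_score()].
#' @param tie How to resolve tied maxima: `"lowest"` (first symbol in
#'   alphabet order; deterministic default) or `"random"` (seeded draw among
#'   the tied symbols).
#' @return An object of class `rngt_candidates`: list with `history`, `h`,
#'   `scores` (named numeric vector over the alphabet) and `argmax` (the
#'   predicted symbol).
#' @examples
#' x <- c(1, 2, 3, 4, 1, 3, 2, 1, 2, 3, 6, 4, 9, 1, 2, 3)
#' candidate_scores(c(1, 2), x)$argmax  # "3": x is built around (1, 2, 3)
#' @export
candidate_scores <- function(history, sources, alphabet = NULL,
                             affinity = c("inv1p", "invcap"), cap = 2,
                             window = c("free", "fixed"),
                             tie = c("lowest", "random")) {
  trials <- as_trial_list(sources, alphabet)
  alphabet <- resolve_alphabet(alphabet, trials)
  history <- as.character(history)
  h <- length(history)
  if (h > 0) enc(history, alphabet, what = "history")
  lens <- vapply(trials, function(t) length(t$sequence), integer(1))
  if (h + 1 > min(lens)) {
    stop(sprintf("history length h = %d requires sources of length >= %d", h, h + 1),
         call. = FALSE)
  }
  codes <- lapply(trials, function(t) enc(t$sequence, alphabet))
  q <- cpp_candidate_q(codes, enc(history, alphabet, what = "history"),
                       length(alphabet), affinity_code(match.arg(affinity)),
                       cap, window_fixed(window))
  names(q) <- unclass(alphabet)
  best <- which(q == max(q))
  pick <- if (tie_code(match.arg(tie)) == 1L && length(best) > 1) {
    best[sample.int(length(best), 1)]
  } else {
    best[1]
  }
  structure(list(history = history, h = h, scores = q,
                 argmax = unclass(alphabet)[pick]),
            class = "rngt_candidates")
}

#' @export
print.rngt_candidates <- function(x, ...) {
  cat(sprintf("<rngt_candidates> h = %d, history (%s) -> predict '%s'\n",
              x$h, paste(x$history, collapse = " "), x$argmax))
  print(round(x$scores, 6))
  invisible(x)
}

#' Exact-hit prediction rate of one sequence on another
#'
#' Uses the pattern statistics of the source sequence(s) to predict the
#' target sequence position by position: at every position
#' `k = h + 1, ..., l` the preceding `h` symbols form the history, all
#' single-symbol extensions are scored against the source via
#' [candidate_scores()], and the argmax is the prediction. The prediction
#' rate is the fraction of exact hits,
#' \eqn{\zeta = hits / (l - h)}; only positions with a full history are
#' evaluated. For iid-uniform sequences over `K` symbols \eqn{\zeta}
#' converges to `1/K` (11.1% for digits 1-9), the chance floor.
#'
#' @param source Source trial(s): [rngt_trial()], [rngt_cohort()], symbol
#'   vector or list of these. Multiple sources are averaged in `q(j)`.
#' @param target Target trial or symbol vector; must be longer than `h`.
#' @param h History length (0-10 is the usual sweep; `h = 0` is the majority
#'   classifier).
#' @param trace If `TRUE`, keep a per-position trace (history, prediction,
#'   actual, hit, and the full `q` matrix as attribute `"q"`).
#' @inheritParams candidate_scores
#' @return An object of class `rngt_rate`: list with `zeta`, `hits`,
#'   `evaluated`, `h`, `source_ids`, `target_id` and optional `trace`
#'   data.frame.
#' @examples
#' cyc <- rep(1:9, 4)
#' prediction_rate(cyc, cyc, h = 2)$zeta  # 1: the cycle is fully predictable
#' @export
prediction_rate <- function(source, target, h, alphabet = NULL,
                            affinity = c("inv1p", "invcap"), cap = 2,
                            window = c("free", "fixed"),
                            tie = c("lowest", "random"), trace = FALSE) {
  src_trials <- as_trial_list(source, alphabet)
  tgt_trials <- as_trial_list(target, alphabet)
  if (length(tgt_trials) != 1) stop("`target` must be a single trial", call. = FALSE)
  tgt <- tgt_trials[[1]]
  alphabet <- resolve_alphabet(alphabet, c(src_trials, tgt_trials))
  h <- as.integer(h)
  if (h < 0) stop("history length h must be >= 0", call. = FALSE)
  lt <- length(tgt$sequence)
  if (lt <= h) {
    stop(sprintf("target length l = %d must exceed history length h = %d", lt, h),
         call. = FALSE)
  }
  lens <- vapply(src_trials, function(t) length(t$sequence), integer(1))
  if (h + 1 > min(lens)) {
    stop(sprintf("history length h = %d requires sources of length >= %d", h, h + 1),
         call. = FALSE)
  }
  src_codes <- lapply(src_trials, function(t) enc(t$sequence, alphabet))
  tgt_codes <- enc(tgt$sequence, alphabet)
  res <- cpp_predict(src_codes, tgt_codes, h, length(alphabet),
                     affinity_code(match.arg(affinity)), cap,
                     window_fixed(window), tie_code(match.arg(tie)), trace)
  out <- list(h = h, hits = res$hits, evaluated = res$evaluated,
              zeta = res$hits / res$evaluated,
              source_ids = vapply(src_trials, trial_label, character(1)),
              target_id = trial_label(tgt))
  if (trace) {
    pos <- (h + 1L):lt
    hist_str <- vapply(pos, function(k) {
      if (h == 0) "" else paste(tgt$sequence[(k - h):(k - 1)], collapse = " ")
    }, character(1))
    predicted <- unclass(alphabet)[res$predicted + 1L]
    tr <- data.frame(position = pos, history = hist_str, predicted = predicted,
                     actual = tgt$sequence[pos],
                     hit = predicted == tgt$sequence[pos],
                     stringsAsFactors = FALSE)
    qm <- res$q
    colnames(qm) <- unclass(alphabet)
    attr(tr, "q") <- qm
    out$trace <- tr
  }
  structure(out, class = "rngt_rate")
}

#' @export
print.rngt_rate <- function(x, ...) {
  cat(sprintf("<rngt_rate> zeta = %.4f (%d/%d hits) | h = %d | %s -> %s\n",
              x$zeta, x$hits, x$evaluated, x$h,
              paste(x$source_ids, collapse = "+"), x$target_id))
  invisible(x)
}
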