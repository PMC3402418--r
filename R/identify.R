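#' Pairwise prediction-rate matrix of a cohort
#'
#' Computes the exact-hit prediction rate \eqn{\zeta} for every ordered pair
#' of distinct trials in a cohort (a trial never predicts itself), and labels
#' each pair as within-subject or between-subject. This is the raw material
#' of the identification analysis: stable individual pattern use should make
#' within-subject entries systematically larger.
#'
#' @param cohort An [rngt_cohort()] with at least 2 trials.
#' @param h History length.
#' @inheritParams prediction_rate
#' @return A data.frame of class `rngt_zeta` with columns `source_subject`,
#'   `source_trial`, `target_subject`, `target_trial`, `zeta`, `within`, and
#'   attribute `h`. See [summary.rngt_zeta()] for cohort-level means.
#' @export
zeta_matrix <- function(cohort, h, affinity = c("inv1p", "invcap"), cap = 2,
                        window = c("free", "fixed"), tie = c("lowest", "random")) {
  stopifnot(inherits(cohort, "rngt_cohort"))
  trials <- cohort$trials
  nt <- length(trials)
  if (nt < 2) stop("a zeta matrix needs a cohort with at least 2 trials", call. = FALSE)
  alphabet <- cohort$alphabet
  codes <- lapply(trials, function(t) enc(t$sequence, alphabet))
  subs <- vapply(trials, function(t) t$subject_id, character(1))
  tris <- vapply(trials, function(t) t$trial_id, character(1))
  aff <- affinity_code(match.arg(affinity))
  fx <- window_fixed(window)
  tc <- tie_code(match.arg(tie))

  rows <- vector("list", nt)
  for (s in seq_len(nt)) {
    others <- setdiff(seq_len(nt), s)
    # one scorer per source: candidate scores are memoized across all of its
    # targets, which shares work at small h where histories repeat
    z <- cpp_zeta_block(codes[s], codes[others], as.integer(h),
                        length(alphabet), aff, cap, fx, tc)
    rows[[s]] <- data.frame(source_subject = subs[s], source_trial = tris[s],
                            target_subject = subs[others],
                            target_trial = tris[others],
                            zeta = as.numeric(z),
                            within = subs[others] == subs[s],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "h") <- as.integer(h)
  class(out) <- c("rngt_zeta", "data.frame")
  out
}

#' Within/between-subject summary of a prediction-rate matrix
#'
#' Means of \eqn{\zeta} over within-subject and between-subject ordered
#' pairs. SEMs are computed across subjects (entries are first averaged per
#' target subject — the subject whose sequence is being predicted — and the
#' SEM is taken over those subject means), matching the convention of
#' reporting cohort error bars across subjects rather than across pairs.
#'
#' @param object An `rngt_zeta` matrix.
#' @param ... Unused.
#' @return One-row data.frame with `h`, `within_mean`, `within_sem`,
#'   `between_mean`, `between_sem`, `gap` (within minus between), `n_within`,
#'   `n_between`.
#' @export
summary.rngt_zeta <- function(object, ...) {
  wi <- object[object$within, ]
  be <- object[!object$within, ]
  by_subject <- function(df) {
    if (nrow(df) == 0) return(numeric(0))
    as.numeric(tapply(df$zeta, df$target_subject, mean))
  }
  wm <- by_subject(wi)
  bm <- by_subject(be)
  data.frame(h = attr(object, "h"),
             within_mean = mean(wi$zeta), within_sem = sem(wm),
             between_mean = mean(be$zeta), between_sem = sem(bm),
             gap = mean(wi$zeta) - mean(be$zeta),
             n_within = nrow(wi), n_between = nrow(be))
}

#' Three-sequence discrimination test
#'
#' Given a reference trial, a second trial from the same subject and one from
#' a different subject, predicts the reference from each candidate and
#' declares the origin correctly identified when
#' \eqn{\zeta_{same} > \zeta_{different}}. Because \eqn{\zeta} lives on the
#' grid of multiples of `1/(l - h)`, exact ties occur with non-negligible
#' probability; the tie policy decides their credit: `"half"` (default, 0.5
#' credit, which calibrates an exchangeable null to exactly 50%), `"strict"`
#' (ties count as failures) or `"random"` (seeded fair coin).
#'
#' @param ref,same,diff [rngt_trial()] objects; `same` must share `ref`'s
#'   subject id (but be a different trial), `diff` must not.
#' @param h History length.
#' @param tie_policy `"half"`, `"strict"` or `"random"`.
#' @inheritParams prediction_rate
#' @return An object of class `rngt_triplet`: list with `zeta_same`,
#'   `zeta_diff`, `tie` (logical) and `correct` (1, 0 or the tie credit).
#' @export
triplet_test <- function(ref, same, diff, h,
                         tie_policy = c("half", "strict", "random"),
                         affinity = c("inv1p", "invcap"), cap = 2,
                         window = c("free", "fixed"), tie = c("lowest", "random")) {
  stopifnot(inherits(ref, "rngt_trial"), inherits(same, "rngt_trial"),
            inherits(diff, "rngt_trial"))
  tie_policy <- match.arg(tie_policy)
  if (same$subject_id != ref$subject_id) {
    stop("`same` must come from the reference subject", call. = FALSE)
  }
  if (trial_label(same) == trial_label(ref)) {
    stop("`same` must be a different trial than the reference", call. = FALSE)
  }
  if (diff$subject_id == ref$subject_id) {
    stop("`diff` must come from a different subject than the reference", call. = FALSE)
  }
  zs <- prediction_rate(same, ref, h, affinity = affinity, cap = cap,
                        window = window, tie = tie)$zeta
  zd <- prediction_rate(diff, ref, h, affinity = affinity, cap = cap,
                        window = window, tie = tie)$zeta
  is_tie <- zs == zd
  correct <- if (zs > zd) 1 else if (!is_tie) 0 else {
    switch(tie_policy, half = 0.5, strict = 0, random = stats::rbinom(1, 1, 0.5))
  }
  structure(list(h = as.integer(h), zeta_same = zs, zeta_diff = zd,
                 tie = is_tie, correct = correct, tie_policy = tie_policy,
                 ref_id = trial_label(ref), same_id = trial_label(same),
                 diff_id = trial_label(diff)),
            class = "rngt_triplet")
}

#' @export
print.rngt_triplet <- function(x, ...) {
  cat(sprintf("<rngt_triplet> h = %d | zeta_same = %.4f vs zeta_diff = %.4f -> credit %.1f\n",
              x$h, x$zeta_same, x$zeta_diff, x$correct))
  invisible(x)
}

#' Subject identification rate over all triplets of a cohort
#'
#' Enumerates every valid (reference, same-subject, different-subject)
#' triplet in the cohort and reports the credited fraction of correct
#' identifications \eqn{\eta(h)}. With the canonical 20 subjects x 2 trials
#' design each reference has 1 same-subject and 38 different-subject
#' candidates, giving 1520 triplets. Chance performance is 50%.
#'
#' @param cohort An [rngt_cohort()] with at least 2 subjects; subjects with
#'   fewer than 2 trials are skipped as references with a warning.
#' @param h History length.
#' @param tie_policy Tie credit, as in [triplet_test()].
#' @param zmat Optional precomputed [zeta_matrix()] for this cohort and `h`
#'   (computed on the fly if missing).
#' @inheritParams prediction_rate
#' @return An object of class `rngt_eta`: list with `h`, `eta`,
#'   `n_triplets`, `n_ties`, `per_subject` (credited rate by reference
#'   subject) and `per_reference` (by reference trial, the per-direction
#'   breakdown).
#' @export
identification_rate <- function(cohort, h,
                                tie_policy = c("half", "strict", "random"),
                                zmat = NULL,
                                affinity = c("inv1p", "invcap"), cap = 2,
                                window = c("free", "fixed"),
                                tie = c("lowest", "random")) {
  stopifnot(inherits(cohort, "rngt_cohort"))
  tie_policy <- match.arg(tie_policy)
  subs <- vapply(cohort$trials, function(t) t$subject_id, character(1))
  if (length(unique(subs)) < 2) {
    stop("identification needs a cohort with at least 2 subjects", call. = FALSE)
  }
  singles <- names(which(table(subs) < 2))
  if (length(singles) > 0) {
    warning("subject(s) with fewer than 2 trials skipped as references: ",
            paste(singles, collapse = ", "), call. = FALSE)
  }
  if (is.null(zmat)) {
    zmat <- zeta_matrix(cohort, h, affinity = affinity, cap = cap,
                        window = window, tie = tie)
  }
  key <- function(ss, st, ts, tt) paste(ss, st, ts, tt, sep = "\r")
  zlook <- stats::setNames(zmat$zeta, key(zmat$source_subject, zmat$source_trial,
                                          zmat$target_subject, zmat$target_trial))

  labels <- vapply(cohort$trials, trial_label, character(1))
  tris <- vapply(cohort$trials, function(t) t$trial_id, character(1))
  rows <- list()
  for (r in seq_along(labels)) {
    same_idx <- which(subs == subs[r] & labels != labels[r])
    if (length(same_idx) == 0) next
    diff_idx <- which(subs != subs[r])
    grid <- expand.grid(s = same_idx, d = diff_idx)
    zs <- zlook[key(subs[grid$s], tris[grid$s], subs[r], tris[r])]
    zd <- zlook[key(subs[grid$d], tris[grid$d], subs[r], tris[r])]
    rows[[length(rows) + 1L]] <- data.frame(
      ref_subject = subs[r], ref_trial = tris[r],
      zeta_same = as.numeric(zs), zeta_diff = as.numeric(zd),
      stringsAsFactors = FALSE)
  }
  tri <- do.call(rbind, rows)
  is_tie <- tri$zeta_same == tri$zeta_diff
  credit <- as.numeric(tri$zeta_same > tri$zeta_diff)
  credit[is_tie] <- switch(tie_policy,
                           half = 0.5,
                           strict = 0,
                           random = stats::rbinom(sum(is_tie), 1, 0.5))
  tri$credit <- credit
  per_subject <- aggregate(credit ~ ref_subject, data = tri, FUN = mean)
  names(per_subject) <- c("subject", "eta")
  per_reference <- aggregate(credit ~ ref_subject + ref_trial, data = tri, FUN = mean)
  names(per_reference) <- c("subject", "ref_trial", "eta")
  structure(list(h = as.integer(h), eta = mean(credit), n_triplets = nrow(tri),
                 n_ties = sum(is_tie), tie_policy = tie_policy,
                 per_subject = per_subject, per_reference = per_reference),
            class = "rngt_eta")
}

#' @export
print.rngt_eta <- function(x, ...) {
  cat(sprintf("<rngt_eta> eta(%d) = %.4f over %d triplets (%d ties, policy '%s')\n",
              x$h, x$eta, x$n_triplets, x$n_ties, x$tie_policy))
  invisible(x)
}
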