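#' A single trial: one generated sequence with its identity
#'
#' A trial is one sequence produced by one subject in one sitting of the task
#' (typically 300 digits at 1 Hz pacing), together with opaque subject and
#' trial labels.
#'
#' @param subject_id,trial_id Opaque labels (coerced to character).
#' @param sequence Vector of alphabet symbols, ordered as generated.
#' @param alphabet An [rngt_alphabet()]; every sequence symbol must belong to it.
#' @return An object of class `rngt_trial` with fields `subject_id`,
#'   `trial_id`, `sequence` (character vector) and `alphabet`.
#' @examples
#' rngt_trial("S1", "t1", c(2, 1, 9, 6, 2, 1, 9, 6))
#' @export
rngt_trial <- function(subject_id, trial_id, sequence, alphabet = rngt_alphabet()) {
  alphabet <- rngt_alphabet(alphabet)
  sequence <- as.character(sequence)
  if (length(sequence) < 1) stop("a trial sequence must have length >= 1", call. = FALSE)
  enc(sequence, alphabet, what = sprintf("trial %s:%s", subject_id, trial_id))
  structure(list(subject_id = as.character(subject_id)[1],
                 trial_id = as.character(trial_id)[1],
                 sequence = sequence,
                 alphabet = alphabet),
            class = "rngt_trial")
}

#' @export
print.rngt_trial <- function(x, ...) {
  l <- length(x$sequence)
  shown <- paste(utils::head(x$sequence, 20), collapse = " ")
  if (l > 20) shown <- paste0(shown, " ...")
  cat(sprintf("<rngt_trial> subject %s, trial %s, l = %d\n  %s\n",
              x$subject_id, x$trial_id, l, shown))
  invisible(x)
}

#' A cohort of trials
#'
#' Bundles trials from one or more subjects over a shared alphabet; the
#' canonical design is 20 subjects with 2 trials of 300 symbols each.
#'
#' @param trials List of [rngt_trial()] objects. `(subject_id, trial_id)`
#'   pairs must be unique and all trials must use `alphabet`.
#' @param alphabet Shared [rngt_alphabet()].
#' @return An object of class `rngt_cohort` with fields `trials` and `alphabet`.
#' @seealso [read_cohort()], [generate_cohort()]
#' @export
rngt_cohort <- function(trials, alphabet = rngt_alphabet()) {
  alphabet <- rngt_alphabet(alphabet)
  if (!is.list(trials) || !all(vapply(trials, inherits, logical(1), "rngt_trial"))) {
    stop("`trials` must be a list of rngt_trial objects", call. = FALSE)
  }
  keys <- vapply(trials, trial_label, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (subject, trial) pair: ", keys[duplicated(keys)][1], call. = FALSE)
  }
  for (tr in trials) {
    if (!identical(unclass(tr$alphabet), unclass(alphabet))) {
      stop("trial ", trial_label(tr), " does not share the cohort alphabet",
           call. = FALSE)
    }
  }
  structure(list(trials = trials, alphabet = alphabet), class = "rngt_cohort")
}

#' @export
print.rngt_cohort <- function(x, ...) {
  subs <- unique(vapply(x$trials, function(t) t$subject_id, character(1)))
  lens <- vapply(x$trials, function(t) length(t$sequence), integer(1))
  cat(sprintf("<rngt_cohort> %d trials from %d subjects, lengths %d-%d, alphabet {%s}\n",
              length(x$trials), length(subs), min(lens), max(lens),
              paste(unclass(x$alphabet), collapse = " ")))
  invisible(x)
}

#' Subject ids of a cohort
#' @param cohort An [rngt_cohort()].
#' @return Character vector of unique subject ids, in first-appearance order.
#' @export
cohort_subjects <- function(cohort) {
  unique(vapply(cohort$trials, function(t) t$subject_id, character(1)))
}

#' Read a cohort manifest CSV
#'
#' The manifest has a header `subject,trial,sequence`, one trial per row,
#' with `sequence` given as space-separated symbol tokens. Malformed rows,
#' out-of-alphabet symbols and duplicate `(subject, trial)` pairs are
#' reported as errors naming the offending line.
#'
#' @param path Path to the manifest CSV.
#' @param alphabet [rngt_alphabet()] the sequences are validated against.
#' @return An [rngt_cohort()]; row order is preserved.
#' @export
read_cohort <- function(path, alphabet = rngt_alphabet()) {
  alphabet <- rngt_alphabet(alphabet)
  if (!file.exists(path)) stop("cohort manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("subject", "trial", "sequence")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns subject,trial,sequence; got: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  trials <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    line <- r + 1L  # header is line 1
    row <- df[r, need]
    if (anyNA(row) || !nzchar(trimws(row$sequence))) {
      stop(sprintf("malformed manifest row at line %d", line), call. = FALSE)
    }
    tokens <- strsplit(trimws(row$sequence), "[[:space:]]+")[[1]]
    idx <- match(tokens, alphabet)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop(sprintf("line %d: symbol '%s' at sequence position %d is not in the alphabet",
                   line, tokens[bad], bad), call. = FALSE)
    }
    trials[[r]] <- rngt_trial(row$subject, row$trial, tokens, alphabet)
  }
  keys <- vapply(trials, trial_label, character(1))
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    stop(sprintf("duplicate (subject, trial) pair '%s' at line %d",
                 dup, which(keys == dup)[2] + 1L), call. = FALSE)
  }
  rngt_cohort(trials, alphabet)
}

#' Write a cohort manifest CSV
#'
#' Inverse of [read_cohort()]: writes one row per trial, preserving trial
#' order, so that `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param cohort An [rngt_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "rngt_cohort"))
  df <- data.frame(
    subject = vapply(cohort$trials, function(t) t$subject_id, character(1)),
    trial = vapply(cohort$trials, function(t) t$trial_id, character(1)),
    sequence = vapply(cohort$trials, function(t) paste(t$sequence, collapse = " "),
                      character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tabular report CSV
#'
#' Reports are written with a header and rows sorted lexicographically by all
#' columns (left to right), so repeated runs produce byte-identical files.
#'
#' @param report A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!is.data.frame(report)) stop("`report` must be a data.frame", call. = FALSE)
  if (nrow(report) > 1) {
    report <- report[do.call(order, unname(as.list(report))), , drop = FALSE]
  }
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
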