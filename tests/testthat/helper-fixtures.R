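# Shared fixtures, built in code.

digits9 <- rngt_alphabet()

make_trial <- function(seq, subject = "S1", trial = "t1", alphabet = digits9) {
  rngt_trial(subject, trial, seq, alphabet)
}

iid_seq <- function(l, K = 9) {
  sample(as.character(seq_len(K)), l, replace = TRUE)
}

# Cohort from a named list of sequences: names are "subject.trial".
cohort_from <- function(sequences, alphabet = digits9) {
  trials <- lapply(names(sequences), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    rngt_trial(parts[1], parts[2], sequences[[nm]], alphabet)
  })
  rngt_cohort(trials, alphabet)
}

# Brute-force anchored distance: explicit minimum over all window ends
# (including the empty window), each window scored by the full-string DP.
brute_anchored <- function(m, z, i) {
  n <- length(m)
  l <- length(z)
  ends <- (i - 1):min(l, i + 2 * n - 1)
  min(vapply(ends, function(e) {
    win <- if (e < i) character(0) else z[i:e]
    dl_distance(m, win)
  }, numeric(1)))
}

# Modal symbol of a sequence with ties broken by alphabet order.
modal_symbol <- function(x, alphabet = digits9) {
  counts <- vapply(unclass(alphabet), function(s) sum(x == s), numeric(1))
  unclass(alphabet)[which.max(counts)]
}
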