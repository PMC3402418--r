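# Internal helpers shared across modules.

# Encode symbol tokens as 0-based integer codes against an alphabet (or, for
# pure distance computations where only equality matters, against the union
# of observed tokens).
enc <- function(tokens, alphabet = NULL, what = "sequence") {
  tokens <- as.character(tokens)
  if (is.null(alphabet)) {
    return(match(tokens, unique(tokens)) - 1L)
  }
  idx <- match(tokens, alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("symbol '%s' at position %d of %s is not in the alphabet [%s]",
                 tokens[bad], bad, what, paste(alphabet, collapse = " ")),
         call. = FALSE)
  }
  idx - 1L
}

# Normalize trial-ish input (rngt_trial, rngt_cohort, bare token vector, or a
# list of those) to a list of rngt_trial objects. Bare vectors are wrapped
# with synthetic ids.
as_trial_list <- function(x, alphabet = NULL) {
  wrap1 <- function(el, k) {
    if (inherits(el, "rngt_trial")) return(el)
    if (is.atomic(el)) {
      ab <- if (is.null(alphabet)) rngt_alphabet() else alphabet
      return(rngt_trial("seq", paste0("s", k), el, ab))
    }
    stop("cannot interpret input as a trial: expected an rngt_trial or a symbol vector",
         call. = FALSE)
  }
  if (inherits(x, "rngt_cohort")) return(x$trials)
  if (inherits(x, "rngt_trial")) return(list(x))
  if (is.atomic(x)) return(list(wrap1(x, 1L)))
  if (is.list(x)) return(Map(wrap1, x, seq_along(x)))
  stop("cannot interpret input as trials", call. = FALSE)
}

# Alphabet resolution order: explicit argument > first trial's own > default.
resolve_alphabet <- function(alphabet, trials) {
  if (!is.null(alphabet)) return(rngt_alphabet(alphabet))
  for (tr in trials) {
    if (inherits(tr, "rngt_trial") && !is.null(tr$alphabet)) return(tr$alphabet)
  }
  rngt_alphabet()
}

trial_label <- function(tr) paste(tr$subject_id, tr$trial_id, sep = ":")

affinity_code <- function(affinity) {
  affinity <- match.arg(affinity, c("inv1p", "invcap"))
  c(inv1p = 0L, invcap = 1L)[[affinity]]
}

window_fixed <- function(window) {
  window <- match.arg(window, c("free", "fixed"))
  window == "fixed"
}

tie_code <- function(tie) {
  tie <- match.arg(tie, c("lowest", "random"))
  c(lowest = 0L, random = 1L)[[tie]]
}

affinity_transform <- function(d, affinity = "inv1p", cap = 2) {
  if (affinity_code(affinity) == 0L) 1 / (1 + d) else ifelse(d == 0, cap, 1 / d)
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulation helpers do not perturb it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Parse CLI-ish history ranges: "3", "0:7", "0,2,4".
parse_h_range <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  x <- as.character(x)
  if (grepl(":", x, fixed = TRUE)) {
    ab <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
    return(seq.int(ab[1], ab[2]))
  }
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}
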