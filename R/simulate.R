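#' Specification of a synthetic sequence generator
#'
#' Three generator families span the data model the analysis assumes:
#' `"iid_uniform"` draws symbols independently and uniformly (the chance
#' null); `"markov"` is a higher-order Markov chain, the formal model of a
#' subject with fixed transition rules; `"pattern_weaver"` emits a dominant
#' base pattern with occasional insertions, substitutions and break-offs to
#' other positions, the phenomenological picture of a subject cycling a
#' favorite motif.
#'
#' `repetition_penalty` models the well-documented human avoidance of
#' immediate repetitions: before each draw the probability of repeating the
#' previous symbol is multiplied by `exp(-penalty)` and the vector is
#' renormalized. It applies to the stochastic-draw generators
#' (`iid_uniform`, `markov`); the pattern weaver's output is pattern-driven
#' and ignores it.
#'
#' @param kind One of `"iid_uniform"`, `"markov"`, `"pattern_weaver"`.
#' @param order Markov order (context length), `>= 1`; `"markov"` only.
#' @param transitions Named list mapping context strings (space-separated
#'   symbol tokens of length `order`) to probability vectors over the
#'   alphabet (non-negative, summing to 1 within 1e-9). Contexts missing
#'   from the table fall back to a uniform draw.
#' @param base_pattern Symbol vector; `"pattern_weaver"` only.
#' @param p_insert,p_substitute,p_break_off Per-emission perturbation
#'   probabilities of the weaver (must sum to at most 1): insert a random
#'   symbol without advancing, substitute a random symbol for the due one, or
#'   break off to a random position of the base pattern.
#' @param repetition_penalty Non-negative; see Details.
#' @return An object of class `rngt_genspec`.
#' @export
generator_spec <- function(kind = c("iid_uniform", "markov", "pattern_weaver"),
                           order = NULL, transitions = NULL, base_pattern = NULL,
                           p_insert = 0.1, p_substitute = 0.05, p_break_off = 0.05,
                           repetition_penalty = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(repetition_penalty) || repetition_penalty < 0) {
    stop("repetition_penalty must be a non-negative number", call. = FALSE)
  }
  spec <- list(kind = kind, repetition_penalty = repetition_penalty)
  if (kind == "markov") {
    if (is.null(order) || order < 1) stop("markov generators need order >= 1", call. = FALSE)
    if (is.null(transitions) || is.null(names(transitions))) {
      stop("markov generators need a named `transitions` list (context -> probabilities)",
           call. = FALSE)
    }
    for (ctx in names(transitions)) {
      p <- transitions[[ctx]]
      nctx <- length(strsplit(ctx, "[[:space:]]+")[[1]])
      if (nctx != order) {
        stop(sprintf("context '%s' has length %d but order is %d", ctx, nctx, order),
             call. = FALSE)
      }
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        stop(sprintf("transition row for context '%s' is not a probability vector", ctx),
             call. = FALSE)
      }
    }
    spec$order <- as.integer(order)
    spec$transitions <- transitions
  } else if (kind == "pattern_weaver") {
    if (is.null(base_pattern) || length(base_pattern) < 1) {
      stop("pattern_weaver generators need a non-empty base_pattern", call. = FALSE)
    }
    probs <- c(p_insert, p_substitute, p_break_off)
    if (any(probs < 0) || sum(probs) > 1) {
      stop("perturbation probabilities must be non-negative and sum to at most 1",
           call. = FALSE)
    }
    spec$base_pattern <- as.character(base_pattern)
    spec$p_insert <- p_insert
    spec$p_substitute <- p_substitute
    spec$p_break_off <- p_break_off
  }
  structure(spec, class = "rngt_genspec")
}

# One symbol draw from a probability vector with repetition avoidance.
draw_symbol <- function(probs, K, last, penalty) {
  if (penalty > 0 && !is.na(last)) {
    probs[last] <- probs[last] * exp(-penalty)
    probs <- probs / sum(probs)
  }
  sample.int(K, 1, prob = probs)
}

#' Generate one synthetic trial
#'
#' Seeded, reproducible sequence generation from a [generator_spec()]. For
#' Markov generators the first `order` symbols (where the context is still
#' incomplete) are padded by uniform draws; repetition avoidance applies to
#' every draw after the first.
#'
#' @param spec An [rngt_genspec][generator_spec()].
#' @param length Sequence length, `>= 1`.
#' @param alphabet Target [rngt_alphabet()].
#' @param seed Integer seed; if `NULL`, the current RNG stream is used.
#' @param subject_id,trial_id Labels for the resulting trial.
#' @return An [rngt_trial()].
#' @examples
#' generate_trial(generator_spec("iid_uniform"), 20, seed = 1)
#' @export
generate_trial <- function(spec, length, alphabet = rngt_alphabet(), seed = NULL,
                           subject_id = "sim", trial_id = "t1") {
  stopifnot(inherits(spec, "rngt_genspec"))
  alphabet <- rngt_alphabet(alphabet)
  length <- as.integer(length)
  if (length < 1) stop("trial length must be >= 1", call. = FALSE)
  K <- base::length(alphabet)
  syms <- unclass(alphabet)
  with_seed(seed, {
    seq_codes <- switch(spec$kind,
      iid_uniform = {
        if (spec$repetition_penalty == 0) {
          sample.int(K, length, replace = TRUE)
        } else {
          out <- integer(length)
          for (t in seq_len(length)) {
            last <- if (t > 1) out[t - 1] else NA_integer_
            out[t] <- draw_symbol(rep(1 / K, K), K, last, spec$repetition_penalty)
          }
          out
        }
      },
      markov = {
        ord <- spec$order
        uni <- rep(1 / K, K)
        out <- integer(length)
        for (t in seq_len(length)) {
          probs <- if (t <= ord) {
            uni  # start-up padding: context not yet complete
          } else {
            ctx <- paste(syms[out[(t - ord):(t - 1)]], collapse = " ")
            p <- spec$transitions[[ctx]]
            if (is.null(p)) uni else p / sum(p)
          }
          last <- if (t > 1) out[t - 1] else NA_integer_
          out[t] <- draw_symbol(probs, K, last, spec$repetition_penalty)
        }
        out
      },
      pattern_weaver = {
        base <- enc(spec$base_pattern, alphabet, what = "base_pattern") + 1L
        B <- base::length(base)
        out <- integer(length)
        ptr <- 1L
        for (t in seq_len(length)) {
          u <- stats::runif(1)
          if (u < spec$p_insert) {
            out[t] <- sample.int(K, 1)  # extra symbol; pattern position held
          } else if (u < spec$p_insert + spec$p_substitute) {
            out[t] <- sample.int(K, 1)
            ptr <- ptr %% B + 1L
          } else if (u < spec$p_insert + spec$p_substitute + spec$p_break_off) {
            ptr <- sample.int(B, 1)  # break off: resume at a random offset
            out[t] <- base[ptr]
            ptr <- ptr %% B + 1L
          } else {
            out[t] <- base[ptr]
            ptr <- ptr %% B + 1L
          }
        }
        out
      })
    rngt_trial(subject_id, trial_id, syms[seq_codes], alphabet)
  })
}

#' Sample per-subject higher-order Markov generators
#'
#' Default "distinct subjects" sampler: each subject receives an order-`order`
#' chain in which every context row is a flat Dirichlet-style draw sharpened
#' so that mass `peak` lands on one randomly chosen successor. This makes
#' subjects generically distinct — each has its own web of preferred
#' transitions — without hand-tuning individual tables.
#'
#' @param n_subjects Number of generators to sample.
#' @param alphabet Alphabet the chains run over.
#' @param order Markov order (default 2).
#' @param peak Probability mass placed on the preferred successor of each
#'   context (default 0.7).
#' @param concentration Gamma shape of the background Dirichlet draw.
#' @param repetition_penalty Passed to each [generator_spec()] (default 1,
#'   a moderate human-like repetition avoidance).
#' @return List of `n_subjects` [generator_spec()] objects. Uses the current
#'   RNG stream; seed it (or call from [generate_cohort()]) for
#'   reproducibility.
#' @export
sample_subject_generators <- function(n_subjects, alphabet = rngt_alphabet(),
                                      order = 2, peak = 0.7, concentration = 0.5,
                                      repetition_penalty = 1) {
  alphabet <- rngt_alphabet(alphabet)
  K <- length(alphabet)
  syms <- unclass(alphabet)
  contexts <- do.call(expand.grid, c(rep(list(syms), order),
                                     stringsAsFactors = FALSE))
  ctx_keys <- apply(contexts[, rev(seq_len(order)), drop = FALSE], 1, paste,
                    collapse = " ")
  lapply(seq_len(n_subjects), function(i) {
    rows <- lapply(ctx_keys, function(ctx) {
      w <- stats::rgamma(K, shape = concentration)
      row <- (1 - peak) * w / sum(w)
      winner <- sample.int(K, 1)
      row[winner] <- row[winner] + peak
      row
    })
    generator_spec("markov", order = order,
                   transitions = stats::setNames(rows, ctx_keys),
                   repetition_penalty = repetition_penalty)
  })
}

#' Specification of a synthetic cohort
#'
#' Defaults mirror the canonical design: 20 subjects, 2 trials per subject,
#' 300 symbols per trial, digits 1-9.
#'
#' @param n_subjects,trials_per_subject,trial_length Design dimensions.
#' @param generators Per-subject generators: a list of `n_subjects`
#'   [generator_spec()]s, a single spec shared by all subjects (e.g. the iid
#'   null), a function `(n_subjects, alphabet) -> list of specs` (a sampler;
#'   called under the master seed), or `NULL` for the default
#'   [sample_subject_generators()] sampler.
#' @param alphabet Shared [rngt_alphabet()].
#' @param seed Master seed; per-trial sub-seeds are derived from it
#'   deterministically.
#' @return An object of class `rngt_cohortspec`.
#' @export
cohort_spec <- function(n_subjects = 20, trials_per_subject = 2,
                        trial_length = 300, generators = NULL,
                        alphabet = rngt_alphabet(), seed = 1) {
  if (trial_length < 1) stop("trial_length must be >= 1", call. = FALSE)
  if (n_subjects < 1 || trials_per_subject < 1) {
    stop("n_subjects and trials_per_subject must be >= 1", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 trial_length = as.integer(trial_length),
                 generators = generators,
                 alphabet = rngt_alphabet(alphabet),
                 seed = as.integer(seed)),
            class = "rngt_cohortspec")
}

#' Generate a synthetic cohort
#'
#' Each subject's generator is reused across that subject's trials — the
#' within-subject stability assumption the identification analysis tests.
#' The cohort is a pure function of its spec: the master seed drives the
#' generator sampler (if any) and the derivation of per-trial sub-seeds.
#'
#' @param spec An [rngt_cohortspec][cohort_spec()].
#' @return An [rngt_cohort()] with subjects `S01, S02, ...` and trials
#'   `t1, t2, ...`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 3, trial_length = 50, seed = 7))
#' coh
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "rngt_cohortspec"))
  ns <- spec$n_subjects
  ntr <- spec$trials_per_subject
  with_seed(spec$seed, {
    gens <- spec$generators
    if (is.null(gens)) {
      gens <- sample_subject_generators(ns, spec$alphabet)
    } else if (is.function(gens)) {
      gens <- gens(ns, spec$alphabet)
    } else if (inherits(gens, "rngt_genspec")) {
      gens <- rep(list(gens), ns)
    }
    if (length(gens) != ns) {
      stop(sprintf("got %d generators for %d subjects", length(gens), ns),
           call. = FALSE)
    }
    subseeds <- sample.int(2147483646L, ns * ntr)
    trials <- vector("list", ns * ntr)
    idx <- 0L
    for (s in seq_len(ns)) {
      for (k in seq_len(ntr)) {
        idx <- idx + 1L
        trials[[idx]] <- generate_trial(gens[[s]], spec$trial_length,
                                        spec$alphabet, seed = subseeds[idx],
                                        subject_id = sprintf("S%02d", s),
                                        trial_id = paste0("t", k))
      }
    }
    rngt_cohort(trials, spec$alphabet)
  })
}

#' Prediction and identification sweep on a synthetic cohort
#'
#' Parameter-recovery harness: generates the cohort, then for each history
#' length computes the full ordered \eqn{\zeta} matrix, its within/between
#' summary and the identification rate \eqn{\eta(h)}.
#'
#' @param spec An [rngt_cohortspec][cohort_spec()].
#' @param h_range Integer vector of history lengths (default `0:7`).
#' @param tie_policy Triplet tie credit, as in [identification_rate()].
#' @inheritParams prediction_rate
#' @return A data.frame of class `rngt_recovery`, one row per `h`, with the
#'   [summary.rngt_zeta()] columns plus `eta` and `n_triplets`. The generated
#'   cohort is attached as attribute `"cohort"`.
#' @export
recovery_experiment <- function(spec, h_range = 0:7,
                                tie_policy = c("half", "strict", "random"),
                                affinity = c("inv1p", "invcap"), cap = 2,
                                window = c("free", "fixed"),
                                tie = c("lowest", "random")) {
  tie_policy <- match.arg(tie_policy)
  cohort <- generate_cohort(spec)
  rows <- lapply(as.integer(h_range), function(h) {
    zm <- zeta_matrix(cohort, h, affinity = affinity, cap = cap,
                      window = window, tie = tie)
    sm <- summary(zm)
    id <- identification_rate(cohort, h, tie_policy = tie_policy, zmat = zm)
    cbind(sm, data.frame(eta = id$eta, n_triplets = id$n_triplets))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cohort") <- cohort
  class(out) <- c("rngt_recovery", "data.frame")
  out
}
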