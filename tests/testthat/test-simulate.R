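test_that("generator specs validate their probability structure", {
  expect_error(generator_spec("markov", order = 2), "transitions")
  expect_error(generator_spec("markov", order = 2,
                              transitions = list("1" = rep(1 / 9, 9))),
               "length 1 but order is 2")
  expect_error(generator_spec("markov", order = 1,
                              transitions = list("1" = rep(0.2, 9))),
               "not a probability vector")
  expect_error(generator_spec("pattern_weaver", base_pattern = c(1, 2),
                              p_insert = 0.6, p_substitute = 0.5),
               "sum to at most 1")
  expect_error(generator_spec("iid_uniform", repetition_penalty = -1),
               "non-negative")
})

test_that("iid draws are uniform across the alphabet", {
  tr <- generate_trial(generator_spec("iid_uniform"), 300, seed = 121)
  counts <- table(factor(tr$sequence, levels = as.character(1:9)))
  se <- sqrt(300 * (1 / 9) * (8 / 9))
  expect_true(all(abs(counts - 300 / 9) < 3 * se))
})

test_that("a deterministic order-2 chain locks into its cycle", {
  succ <- function(s) as.character(as.integer(s) %% 9 + 1)
  ctxs <- expand.grid(a = as.character(1:9), b = as.character(1:9),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(ctxs)), function(k) {
    p <- rep(0, 9)
    p[as.integer(succ(ctxs$b[k]))] <- 1
    p
  })
  spec <- generator_spec("markov", order = 2,
                         transitions = setNames(rows, paste(ctxs$a, ctxs$b)))
  tr <- generate_trial(spec, 60, seed = 131)
  s <- tr$sequence
  # after the uniform start-up padding every step follows the cycle
  expect_identical(s[3:60], vapply(s[2:59], succ, character(1), USE.NAMES = FALSE))
})

test_that("repetition penalty suppresses immediate repeats", {
  reps <- vapply(c(0, 3), function(pen) {
    tr <- generate_trial(generator_spec("iid_uniform", repetition_penalty = pen),
                         2000, seed = 141)
    x <- tr$sequence
    sum(x[-1] == x[-length(x)])
  }, numeric(1))
  expect_gt(reps[1], 150)      # unpenalized: ~1/9 of 1999 steps
  expect_lt(reps[2], reps[1] / 3)
})

test_that("the pattern weaver produces a detectably dominant pattern", {
  spec <- generator_spec("pattern_weaver", base_pattern = c(2, 1, 9, 6),
                         p_insert = 0.1, p_substitute = 0.05, p_break_off = 0.05)
  woven <- generate_trial(spec, 300, seed = 151)
  s_woven <- pattern_score(c(2, 1, 9, 6), woven)$value
  set.seed(152)
  s_iid <- replicate(100, pattern_score(c(2, 1, 9, 6), iid_seq(300))$value)
  expect_gt(s_woven, quantile(s_iid, 0.95))
})

test_that("cohorts are pure functions of their spec", {
  spec <- cohort_spec(n_subjects = 4, trial_length = 50, seed = 161)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(lapply(a$trials, `[[`, "sequence"),
                   lapply(b$trials, `[[`, "sequence"))
  c_ <- generate_cohort(cohort_spec(n_subjects = 4, trial_length = 50, seed = 162))
  expect_false(identical(lapply(a$trials, `[[`, "sequence"),
                         lapply(c_$trials, `[[`, "sequence")))
})

test_that("the default cohort mirrors the canonical design", {
  coh <- generate_cohort(cohort_spec(seed = 171))
  expect_length(coh$trials, 40L)
  expect_length(cohort_subjects(coh), 20L)
  expect_true(all(vapply(coh$trials, function(t) length(t$sequence), integer(1)) == 300L))
  per_subject <- table(vapply(coh$trials, function(t) t$subject_id, character(1)))
  expect_true(all(per_subject == 2L))
})

test_that("within-subject prediction is bracketed by chance and the Bayes ceiling", {
  # explicit order-2 chain: every context has one successor carrying mass 0.85,
  # so no exact-hit predictor can beat 0.85 at h >= 2. The affinity-based
  # predictor lands well above chance but below that ceiling: its candidate
  # scores mix the conditional signal at context occurrences with each
  # pattern's global frequency of approximate matches.
  peak <- 0.85
  ctxs <- expand.grid(a = 1:9, b = 1:9)
  rows <- lapply(seq_len(nrow(ctxs)), function(k) {
    p <- rep((1 - peak) / 8, 9)
    winner <- (ctxs$a[k] + 2 * ctxs$b[k]) %% 9 + 1
    p[winner] <- peak
    p
  })
  spec <- generator_spec("markov", order = 2,
                         transitions = setNames(rows, paste(ctxs$a, ctxs$b)))
  l <- 800
  a <- generate_trial(spec, l, seed = 181, subject_id = "S1", trial_id = "t1")
  b <- generate_trial(spec, l, seed = 182, subject_id = "S1", trial_id = "t2")
  zeta <- prediction_rate(a, b, h = 2)$zeta
  se <- sqrt(peak * (1 - peak) / (l - 2))
  expect_lt(zeta, peak + 3 * se)  # the analytic ceiling holds
  expect_gt(zeta, 0.25)           # and far more than the 1/9 chance rate
})

test_that("the recovery sweep reproduces the expected qualitative shapes", {
  rec <- recovery_experiment(cohort_spec(n_subjects = 5, trial_length = 120,
                                         seed = 191), h_range = 0:3)
  expect_identical(rec$h, 0:3)
  expect_true(all(c("within_mean", "within_sem", "between_mean", "between_sem",
                    "gap", "eta", "n_triplets") %in% names(rec)))
  # within-subject rate rises as the history grows toward the chain order...
  expect_true(all(diff(rec$within_mean[rec$h <= 2]) > 0))
  # ...and stays near its plateau beyond it
  expect_gt(min(rec$within_mean[rec$h >= 2]), 0.7 * max(rec$within_mean))

  null_rec <- recovery_experiment(cohort_spec(n_subjects = 4, trial_length = 200,
                                              generators = generator_spec("iid_uniform"),
                                              seed = 192), h_range = c(0, 3))
  expect_true(all(abs(null_rec$within_mean - 1 / 9) < 0.08))
  expect_true(all(abs(null_rec$between_mean - 1 / 9) < 0.04))
})
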