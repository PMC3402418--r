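test_that("zeta matrix enumerates all ordered distinct pairs", {
  set.seed(91)
  coh <- cohort_from(list(S1.t1 = iid_seq(50), S1.t2 = iid_seq(50),
                          S2.t1 = iid_seq(50), S2.t2 = iid_seq(50)))
  zm <- zeta_matrix(coh, h = 1)
  expect_identical(nrow(zm), 12L)  # 4 * 3 ordered pairs
  # a trial never predicts itself
  expect_false(any(zm$source_subject == zm$target_subject &
                     zm$source_trial == zm$target_trial))
  expect_identical(sum(zm$within), 4L)
  expect_true(all(zm$zeta >= 0 & zm$zeta <= 1))
  sm <- summary(zm)
  expect_identical(sm$n_within, 4L)
  expect_identical(sm$n_between, 8L)
  expect_equal(sm$gap, sm$within_mean - sm$between_mean)

  expect_error(zeta_matrix(rngt_cohort(list(make_trial(iid_seq(10))))),
               "at least 2 trials")
})

test_that("triplets separate a patterned subject from an iid impostor", {
  ref <- make_trial(rep(as.character(1:9), 5), "S1", "t1")
  same <- make_trial(rep(as.character(1:9), 5), "S1", "t2")
  set.seed(101)
  diff <- make_trial(iid_seq(45), "S2", "t1")
  out <- triplet_test(ref, same, diff, h = 2)
  expect_equal(out$zeta_same, 1)
  expect_lt(out$zeta_diff, 0.4)
  expect_identical(out$correct, 1)
})

test_that("forced ties are credited per policy", {
  z <- iid_seq(30)
  ref <- make_trial(z, "S1", "t1")
  same <- make_trial(z, "S1", "t2")
  diff <- make_trial(z, "S2", "t1")
  half <- triplet_test(ref, same, diff, h = 2, tie_policy = "half")
  expect_true(half$tie)
  expect_identical(half$correct, 0.5)
  expect_identical(triplet_test(ref, same, diff, h = 2, tie_policy = "strict")$correct, 0)
  set.seed(1)
  expect_true(triplet_test(ref, same, diff, h = 2, tie_policy = "random")$correct
              %in% c(0L, 1L))
})

test_that("triplet subject relations are enforced", {
  a <- make_trial(iid_seq(20), "S1", "t1")
  b <- make_trial(iid_seq(20), "S1", "t2")
  c_ <- make_trial(iid_seq(20), "S2", "t1")
  expect_error(triplet_test(a, c_, c_, h = 1), "reference subject")
  expect_error(triplet_test(a, a, c_, h = 1), "different trial")
  expect_error(triplet_test(a, b, b, h = 1), "different subject")
})

test_that("identification enumerates every valid triplet", {
  set.seed(111)
  seqs <- list(S1.t1 = iid_seq(40), S1.t2 = iid_seq(40),
               S2.t1 = iid_seq(40), S2.t2 = iid_seq(40),
               S3.t1 = iid_seq(40), S3.t2 = iid_seq(40),
               S4.t1 = iid_seq(40), S4.t2 = iid_seq(40))
  coh <- cohort_from(seqs)
  id <- identification_rate(coh, h = 1)
  # 8 references x 1 same-candidate x 6 different-subject candidates
  expect_identical(id$n_triplets, 48L)
  expect_identical(nrow(id$per_subject), 4L)
  expect_identical(nrow(id$per_reference), 8L)
  expect_true(id$eta >= 0 && id$eta <= 1)

  # a lone-trial subject is skipped as reference but still serves as impostor
  seqs$S5.t1 <- iid_seq(40)
  coh5 <- cohort_from(seqs)
  expect_warning(id5 <- identification_rate(coh5, h = 1), "S5")
  expect_identical(id5$n_triplets, 8L * 7L)

  one_subj <- cohort_from(list(S1.t1 = iid_seq(20), S1.t2 = iid_seq(20)))
  expect_error(identification_rate(one_subj, h = 1), "at least 2 subjects")
})

test_that("an exchangeable cohort calibrates to the chance level", {
  coh <- generate_cohort(cohort_spec(n_subjects = 8, trial_length = 300,
                                     generators = generator_spec("iid_uniform"),
                                     seed = 5))
  zm <- zeta_matrix(coh, h = 3)
  p <- 1 / 9
  se_pair <- sqrt(p * (1 - p) / (300 - 3))
  expect_lt(abs(mean(zm$zeta[zm$within]) - p), 3 * se_pair / sqrt(sum(zm$within)))
  expect_lt(abs(mean(zm$zeta[!zm$within]) - p), 3 * se_pair / sqrt(sum(!zm$within)))
  id <- identification_rate(coh, h = 3, tie_policy = "half", zmat = zm)
  expect_lt(abs(id$eta - 0.5), 3 * 0.5 / sqrt(id$n_triplets))
})

test_that("within-subject prediction beats between on a patterned cohort", {
  coh <- generate_cohort(cohort_spec(n_subjects = 6, trial_length = 150, seed = 6))
  sm <- summary(zeta_matrix(coh, h = 3))
  expect_gt(sm$within_mean, sm$between_mean)
  expect_false(is.na(sm$within_sem))
  expect_false(is.na(sm$between_sem))
})

test_that("sharper per-subject chains never hurt identification", {
  etas <- vapply(c(0.25, 0.55, 0.85), function(peak) {
    gens <- local({
      p <- peak
      function(n, ab) sample_subject_generators(n, ab, peak = p)
    })
    coh <- generate_cohort(cohort_spec(n_subjects = 6, trial_length = 200,
                                       generators = gens, seed = 13))
    identification_rate(coh, h = 3)$eta
  }, numeric(1))
  expect_true(all(diff(etas) >= 0))
})
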