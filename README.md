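# rngtpatterns

Pattern-based prediction and identification for random number generation
tasks (RNGT), in which a subject repeatedly picks digits (typically 1–9)
"at random". Humanly generated sequences are far from random: people avoid
repetitions and lean on short recurring patterns. If those patterns come
from stable, person-specific transition rules, they can be used to predict
the next digit of a sequence — and to recognize *who* produced a sequence.
This package is aimed at researchers in neuropsychology and behavioral
biometrics who want a pattern-level alternative to classical randomness
indices.

## The method

For a pattern *m* (an n-tuple over the digit alphabet *D*) and a sequence
*z* of length *l*, an **affinity score** measures how strongly the pattern
and its close variants are represented in the sequence:

```
s(m, z) = (1/l) * sum_{i=1..l} a(d_i),    a(d) = 1/(1+d)
```

where *d_i* is the Damerau–Levenshtein distance (insertions, deletions,
substitutions, adjacent transpositions; optimal-string-alignment regime)
between the pattern and the best-matching window of *z* starting at
position *i* (free end). A perfect match contributes 1; every additional
edit discounts the contribution.

**Prediction.** At each position of a target sequence, the preceding *h*
symbols (the history) are extended by every candidate digit *j* and scored
against a source sequence: `q(j) = s((history, j), x)`. The argmax of
`q(j)` is the prediction; `h = 0` reduces to a majority classifier. The
exact-hit rate `zeta(x, y, h) = hits / (l - h)` calibrates to 1/9 ≈ 11% on
independent uniform digit sequences.

**Identification.** Given a reference trial, a second trial of the same
subject and one of a different subject, the origin is correctly identified
when `zeta_same > zeta_diff`. The rate `eta(h)` over all such triplets has
chance level 50%.

Because the 20-subject human cohort behind these statistics was never
deposited, the package ships seeded synthetic generators (iid null,
higher-order Markov chains with repetition avoidance, dominant-pattern
weavers) that reproduce the chance baselines and the qualitative
within/between-subject structure.

## Worked example

The prediction mechanics on a 16-digit source built around the pattern
(1, 2, 3), predicting the continuation of a target ending in (1, 2):

```r
library(rngtpatterns)
x <- c(1, 2, 3, 4, 1, 3, 2, 1, 2, 3, 6, 4, 9, 1, 2, 3)
candidate_scores(c("1", "2"), x)
#> <rngt_candidates> h = 2, history (1 2) -> predict '3'
#>        1        2        3        4        5        6        7        8
#> 0.380208 0.359375 0.515625 0.359375 0.333333 0.343750 0.333333 0.333333
#>        9
#> 0.343750
```

Every candidate extension of the history is scored against the source; the
digit completing the dominant pattern wins clearly (0.516 vs 0.380 for the
runner-up). Candidates never seen after (1, 2) still get a floor score —
that is the approximate-matching at work.

At cohort scale, with six simulated subjects (order-2 Markov chains with
person-specific preferred transitions, two 300-digit trials each):

```r
coh <- generate_cohort(cohort_spec(n_subjects = 6, trial_length = 300, seed = 42))
summary(zeta_matrix(coh, h = 3))
#>   h within_mean within_sem between_mean between_sem  gap n_within n_between
#> 1 3       0.407     0.0256        0.127     0.00825 0.28       12       120

identification_rate(coh, h = 3)
#> <rngt_eta> eta(3) = 1.0000 over 120 triplets (0 ties, policy 'half')
```

A subject's own second trial predicts 41% of their digits at history 3,
while another subject's trial predicts only 13% — barely above the 11%
chance floor — and that separation identifies the impostor sequence in
every one of the 120 triplets. `run_experiment()` sweeps `h`, writes all
tables as CSV and optionally plots the within/between curves and `eta(h)`.

## Command line

A thin Rscript CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rngtpatterns.R", package = "rngtpatterns"))')
Rscript "$CLI" simulate --subjects 20 --length 300 --seed 17 --output cohort.csv
Rscript "$CLI" score --pattern 2,1,9,6 --sequences cohort.csv
Rscript "$CLI" predict --sequences cohort.csv --source S01:t1 --target S01:t2 --history 7
Rscript "$CLI" experiment --cohort cohort.csv --history 0:7 --output report/
```

Cohorts are CSV manifests (`subject,trial,sequence`, space-separated
digits); configs may be YAML or JSON.

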