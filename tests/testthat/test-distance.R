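test_that("edit distance reproduces the canonical examples", {
  expect_identical(dl_distance(c(2, 1, 9, 6), c(2, 1, 9, 6)), 0L)
  expect_identical(dl_distance(c(2, 1, 9, 6), c(2, 1, 6)), 1L)   # deletion
  expect_identical(dl_distance(c(2, 1, 9, 6), c(2, 1, 5, 9, 6)), 1L)  # insertion
  expect_identical(dl_distance(c(1, 2), c(2, 1)), 1L)            # transposition
  expect_identical(dl_distance(c(1, 2, 3, 4), c(5, 6, 7, 8)), 4L)  # fully disjoint
  expect_identical(dl_distance(character(0), c(1, 2, 3)), 3L)
  expect_identical(dl_distance(character(0), character(0)), 0L)
})

test_that("edit distance satisfies its metric-style invariants", {
  set.seed(101)
  for (r in 1:300) {
    la <- sample(0:8, 1)
    lb <- sample(0:8, 1)
    a <- sample(as.character(1:4), la, replace = TRUE)
    b <- sample(as.character(1:4), lb, replace = TRUE)
    d <- dl_distance(a, b)
    expect_identical(dl_distance(a, a), 0L)
    expect_identical(dl_distance(b, a), d)                 # symmetry
    expect_gte(d, abs(la - lb))
    expect_lte(d, max(la, lb))
    if (d == 0L) expect_identical(a, b)
  }
})

test_that("transpositions never increase the distance relative to plain Levenshtein", {
  set.seed(55)
  for (r in 1:200) {
    a <- sample(letters[1:5], sample(0:7, 1), replace = TRUE)
    b <- sample(letters[1:5], sample(0:7, 1), replace = TRUE)
    lev <- utils::adist(paste(a, collapse = ""), paste(b, collapse = ""))[1, 1]
    expect_lte(dl_distance(a, b), lev)
  }
})

test_that("the DP agrees with the exhaustive recursive oracle", {
  # exhaustive over all short pairs on a 2-symbol alphabet
  for (la in 0:3) {
    for (lb in 0:3) {
      grids <- expand.grid(rep(list(c("1", "2")), la + lb),
                           stringsAsFactors = FALSE)
      if (nrow(grids) == 0) grids <- data.frame(row.names = 1)
      for (g in seq_len(nrow(grids))) {
        toks <- as.character(unlist(grids[g, ], use.names = FALSE))
        a <- toks[seq_len(la)]
        b <- toks[la + seq_len(lb)]
        expect_identical(dl_distance(a, b), as.integer(oracle_distance(a, b)))
      }
    }
  }
  # large random sample on a 3-symbol alphabet, lengths <= 5
  set.seed(77)
  for (r in 1:1000) {
    a <- sample(as.character(1:3), sample(0:5, 1), replace = TRUE)
    b <- sample(as.character(1:3), sample(0:5, 1), replace = TRUE)
    expect_identical(dl_distance(a, b), as.integer(oracle_distance(a, b)))
  }
})

test_that("the oracle refuses strings beyond its exhaustive range", {
  expect_error(oracle_distance(rep("1", 7), "1"), "length <= 6")
})

test_that("anchored distance reproduces its defining examples", {
  expect_identical(anchored_distance(c(1, 2, 3), c(1, 2, 3, 9, 9), 1), 0L)
  # deleting the leading 9 converts the pattern into the window
  expect_identical(anchored_distance(c(1, 2, 3), c(9, 1, 2, 3, 9), 1), 1L)
  # no shared symbols: cost is n at every start
  z <- rep(c(5, 6, 7, 8), 5)
  for (i in c(1, 7, 20)) {
    expect_identical(anchored_distance(c(1, 2, 3, 4), z, i), 4L)
  }
  expect_error(anchored_distance(c(1, 2), c(1, 2, 3), 0), "1..3")
  expect_error(anchored_distance(c(1, 2), c(1, 2, 3), 4), "1..3")
})

test_that("free-end anchored distance equals the brute-force window minimum", {
  set.seed(202)
  for (r in 1:120) {
    n <- sample(1:4, 1)
    l <- sample(n:12, 1)
    m <- sample(as.character(1:3), n, replace = TRUE)
    z <- sample(as.character(1:3), l, replace = TRUE)
    prof <- anchored_profile(m, z)
    for (i in seq_len(l)) {
      expect_identical(prof[i], as.integer(brute_anchored(m, z, i)))
    }
  }
})

test_that("the window minimum can only improve on the full fixed window", {
  set.seed(303)
  for (r in 1:100) {
    n <- sample(2:5, 1)
    l <- sample((n + 2):20, 1)
    m <- sample(as.character(1:4), n, replace = TRUE)
    z <- sample(as.character(1:4), l, replace = TRUE)
    i <- sample(seq_len(l - n + 1), 1)
    expect_lte(anchored_distance(m, z, i), dl_distance(m, z[i:(i + n - 1)]))
  }
})

test_that("the fixed-window variant scores exactly the length-n window", {
  set.seed(404)
  m <- sample(as.character(1:4), 3, replace = TRUE)
  z <- sample(as.character(1:4), 15, replace = TRUE)
  prof <- anchored_profile(m, z, window = "fixed")
  for (i in seq_along(z)) {
    win <- z[i:min(length(z), i + 2)]
    expect_identical(prof[i], dl_distance(m, win))
  }
})
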