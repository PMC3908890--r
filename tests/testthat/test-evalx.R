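test_that("overlap_score follows |A.B|^2/(|A||B|)", {
  expect_equal(overlap_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_score(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_score(c("a", "b", "c", "d"), c("a", "b")), 0.5)
  # symmetric; duplicates ignored
  expect_equal(overlap_score(c("a", "a", "b"), c("b", "c")),
               overlap_score(c("b", "c"), c("a", "b")))
  expect_error(overlap_score(character(0), "a"), "empty")
})

test_that("overlap_score is 1 iff equal and 0 iff disjoint (property)", {
  set.seed(901)
  pool <- letters
  for (i in 1:50) {
    a <- sample(pool, sample(2:8, 1))
    b <- sample(pool, sample(2:8, 1))
    os <- overlap_score(a, b)
    expect_gte(os, 0); expect_lte(os, 1)
    expect_equal(os == 1, setequal(a, b))
    expect_equal(os == 0, length(intersect(a, b)) == 0)
  }
})

test_that("merge_time_clusters pools, dedupes and merges high-overlap pairs", {
  # identical cluster at two time points -> single copy
  out <- merge_time_clusters(list(list(c("a", "b", "c")),
                                  list(c("c", "b", "a"))))
  expect_equal(out, list(c("a", "b", "c")))

  # OS 0.75 < 0.8: kept separate at the default
  out2 <- merge_time_clusters(list(list(c("a", "b", "c")),
                                   list(c("a", "b", "c", "d"))))
  expect_length(out2, 2L)

  # OS 16/20 = 0.8: merged into the union
  out3 <- merge_time_clusters(list(list(c("a", "b", "c", "d")),
                                   list(c("a", "b", "c", "d", "e"))))
  expect_equal(out3, list(c("a", "b", "c", "d", "e")))
})

test_that("merged output has no duplicates and no pair above the merge threshold", {
  set.seed(902)
  for (trial in 1:10) {
    per_time <- replicate(4, replicate(6, sample(letters[1:12], sample(3:6, 1)),
                                       simplify = FALSE), simplify = FALSE)
    out <- merge_time_clusters(per_time, merge_os = 0.8)
    keys <- vapply(out, function(s) paste(sort(s), collapse = "|"), "")
    expect_equal(anyDuplicated(keys), 0L)
    if (length(out) >= 2) {
      for (i in seq_along(out)[-1])
        for (j in seq_len(i - 1))
          expect_lt(overlap_score(out[[i]], out[[j]]), 0.8)
    }
  }
})

test_that("evaluate counts matches and computes both metric conventions", {
  known <- list(c("a", "b", "c", "d"), c("e", "f", "g"))
  pred <- list(c("a", "b", "c"), c("x", "y"))
  # enumeration: only OS({abc},{abcd}) = 9/12 = 0.75 reaches 0.2
  r <- evaluate(pred, known, os_threshold = 0.2, metric_mode = "match_fraction")
  expect_equal(r$n_matched_known, 1L)
  expect_equal(r$n_matched_predicted, 1L)
  expect_equal(r$sn, 0.5)
  expect_equal(r$sp, 0.5)
  expect_equal(r$f_measure, 0.5)

  # identical prediction: perfect in both modes
  for (mode in c("match_fraction", "brohee")) {
    rp <- evaluate(known, known, metric_mode = mode)
    expect_equal(c(rp$sn, rp$sp, rp$f_measure), c(1, 1, 1))
    expect_equal(rp$n_matched_known_exact, 2L)
  }

  # brohee convention on the asymmetric example:
  # sn = (3 + 0)/(4 + 3); ppv = (3 + 0)/(3 + 0)
  rb <- evaluate(list(c("a", "b", "c")), known, metric_mode = "brohee")
  expect_equal(rb$sn, 3 / 7)
  expect_equal(rb$sp, 1)

  # no predictions: sp = 0, f = 0 by convention
  r0 <- evaluate(list(), known)
  expect_equal(c(r0$sp, r0$f_measure), c(0, 0))
  expect_error(evaluate(pred, list()), "empty")
})

test_that("raising the OS threshold never increases matched counts", {
  set.seed(903)
  known <- replicate(8, sample(letters, sample(3:6, 1)), simplify = FALSE)
  pred <- replicate(10, sample(letters, sample(2:6, 1)), simplify = FALSE)
  prev <- Inf
  for (th in c(0.1, 0.2, 0.5, 1)) {
    r <- evaluate(pred, known, os_threshold = th, metric_mode = "match_fraction")
    expect_lte(r$n_matched_known, prev)
    prev <- r$n_matched_known
  }
})

test_that("complex files round-trip through read/write", {
  f <- withr::local_tempfile()
  sets <- list(c("a", "b", "c"), c("d", "e"))
  write_complexes(sets, f)
  expect_equal(read_complexes(f), sets)
  # duplicate lines collapse on read
  writeLines(c("a b c", "c b a", "", "d e"), f)
  expect_equal(read_complexes(f), list(c("a", "b", "c"), c("d", "e")))
})
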