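# flag_noise / filter_matrix operate on a screen table + matrix; build
# both directly so labels are controlled.
make_screen <- function(ids, labels) {
  data.frame(gene_id = ids, min_p_value = 0.5, best_order = 1L,
             label = labels, degenerate = FALSE, stringsAsFactors = FALSE)
}

test_that("absolute mode flags time-independent genes below the mean cutoff", {
  means <- c(0.1, 0.4, 0.6, 2.0)
  expr <- expr_matrix(lapply(means, rep, 36))
  screen <- make_screen(rownames(expr), rep("time_independent", 4))
  d <- flag_noise(screen, expr, mode = "absolute", threshold = 0.5)
  expect_equal(d$is_noise, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(d$mean_expression, means)

  # strict comparison: a gene exactly at the threshold is kept
  expr2 <- expr_matrix(list(rep(0.5, 36)))
  d2 <- flag_noise(make_screen("g1", "time_independent"), expr2,
                   mode = "absolute", threshold = 0.5)
  expect_false(d2$is_noise)
})

test_that("time-dependent genes are never noise, whatever their mean", {
  expr <- expr_matrix(list(rep(0.01, 36), rep(0.01, 36)))
  screen <- make_screen(rownames(expr), c("time_dependent", "time_independent"))
  d <- flag_noise(screen, expr, mode = "absolute", threshold = 0.5)
  expect_equal(d$is_noise, c(FALSE, TRUE))
  expect_true(all(d$is_noise <= d$is_time_independent))  # noise => ti
})

test_that("quantile mode flags the lowest fraction of time-independent means", {
  set.seed(501)
  means <- sample(seq(0.1, 10, length.out = 100))
  expr <- expr_matrix(lapply(means, rep, 36))
  screen <- make_screen(rownames(expr), rep("time_independent", 100))
  d <- flag_noise(screen, expr, mode = "quantile", threshold = 0.15)
  expect_equal(sum(d$is_noise), 15L)
  expect_equal(sort(d$mean_expression[d$is_noise]),
               sort(means)[1:15])

  # boundary ties are all included
  tied <- c(1, 1, 1, 1, 5, 6, 7, 8, 9, 10)
  expr_t <- expr_matrix(lapply(tied, rep, 12))
  d_t <- flag_noise(make_screen(rownames(expr_t), rep("time_independent", 10)),
                    expr_t, mode = "quantile", threshold = 0.2)
  expect_equal(sum(d_t$is_noise), 4L)   # floor(0.2*10)=2 but all four 1s tie

  expect_error(flag_noise(screen, expr, mode = "quantile", threshold = 1.5),
               "quantile threshold")
})

test_that("raising the absolute threshold never shrinks the noise set", {
  set.seed(502)
  expr <- expr_matrix(lapply(runif(50, 0, 2), function(m) rep(m, 36)))
  screen <- make_screen(rownames(expr),
                        sample(c("time_dependent", "time_independent"), 50,
                               replace = TRUE))
  prev <- rep(FALSE, 50)
  for (th in seq(0, 2, 0.25)) {
    cur <- flag_noise(screen, expr, mode = "absolute", threshold = th)$is_noise
    expect_true(all(prev <= cur))
    prev <- cur
  }
})

test_that("filter_matrix drops flagged rows and preserves order", {
  expr <- expr_matrix(lapply(1:10, function(i) rep(i, 12)))
  screen <- make_screen(rownames(expr), rep("time_independent", 10))
  d <- flag_noise(screen, expr, mode = "absolute", threshold = 3.5)
  out <- filter_matrix(expr, d, quiet = TRUE)
  expect_equal(rownames(out), sprintf("g%d", 4:10))

  # no gene flagged: identical matrix
  none <- flag_noise(screen, expr, mode = "absolute", threshold = 0)
  expect_identical(filter_matrix(expr, none, quiet = TRUE), expr)

  # everything flagged: empty matrix plus warning
  all_ <- flag_noise(screen, expr, mode = "absolute", threshold = 100)
  expect_warning(res <- filter_matrix(expr, all_, quiet = TRUE),
                 "all genes flagged")
  expect_equal(nrow(res), 0L)

  # missing decision is an error
  expect_error(filter_matrix(expr, d[-1, ], quiet = TRUE), "no noise decision")
})
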