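test_that("fit_ar solves the lag-design normal equations", {
  # exact AR(1) relation x_m = 2 x_{m-1}: hand solution beta = (0, 2), rss 0
  f <- fit_ar(c(1, 2, 4, 8, 16), 1)
  expect_true(f$rank_ok)
  expect_equal(f$coefficients, c(0, 2))
  expect_equal(f$residual_variance, 0)
  expect_equal(f$n_obs, 4L)

  # constant series: lag column collinear with the intercept
  expect_false(fit_ar(c(3, 3, 3, 3, 3), 1)$rank_ok)

  # long AR(1) realisation: coefficient recovered near truth and the
  # whole fit agrees with an independent lm() oracle
  set.seed(401)
  x <- numeric(200)
  x[1] <- 2.5
  for (m in 2:200) x[m] <- 0.5 + 0.8 * x[m - 1] + rnorm(1, 0, 0.1)
  f <- fit_ar(x, 1)
  expect_lt(abs(f$coefficients[2] - 0.8), 0.05)
  o <- oracle_ar_lm(x, 1)
  expect_equal(f$coefficients, o$coefficients, tolerance = 1e-10)
  expect_equal(f$residual_variance, o$residual_variance, tolerance = 1e-10)
})

test_that("fit_ar agrees with the least-squares oracle on random full-rank instances", {
  set.seed(402)
  for (i in 1:60) {
    M <- sample(12:60, 1)
    p <- sample.int(min(6L, (M - 2L) %/% 2L), 1)
    x <- rnorm(M, mean = 3)
    f <- fit_ar(x, p)
    o <- oracle_ar_lm(x, p)
    expect_equal(f$coefficients, o$coefficients, tolerance = 1e-8)
    expect_equal(f$residual_variance, o$residual_variance, tolerance = 1e-8)
  }
})

test_that("fit_ar rejects invalid orders and bad data", {
  expect_error(fit_ar(c(1, 2, 3, 4, 5), 3), "invalid AR order")
  expect_error(fit_ar(c(1, 2, 3, 4, 5), 0), "invalid AR order")
  expect_error(fit_ar(c(1, NA, 3, 4, 5), 1), "non-finite")
})

test_that("fit_constant is the mean/ML-variance of the response window", {
  # last M-p values 2,4,4,2 -> mean 3, ML variance 1
  f <- fit_constant(c(9, 2, 4, 4, 2), 1)
  expect_equal(f$beta0, 3)
  expect_equal(f$residual_variance, 1)
  expect_equal(f$n_obs, 4L)

  f0 <- fit_constant(rep(7, 10), 2)
  expect_equal(f0$beta0, 7)
  expect_equal(f0$residual_variance, 0)

  set.seed(403)
  big <- fit_constant(rnorm(10000), 1)
  expect_lt(abs(big$beta0), 0.05)
  expect_lt(abs(big$residual_variance - 1), 0.05)
})

test_that("f_test handles the regular and degenerate regimes", {
  set.seed(404)
  x <- rnorm(36)
  ot <- f_test(fit_ar(x, 1), fit_constant(x, 1))
  # hand arithmetic: F = ((M-2p-1)/p) * (ratio - 1) with (1, 33) df
  ratio <- fit_constant(x, 1)$residual_variance / fit_ar(x, 1)$residual_variance
  expect_equal(ot$f_stat, 33 * (ratio - 1))
  expect_equal(ot$df, c(1L, 33L))
  expect_equal(ot$p_value, pf(ot$f_stat, 1, 33, lower.tail = FALSE))
  # lambda identity: Lambda = (s2/s2c)^((M-p)/2) <= 1
  expect_equal(ot$lambda_ratio, (1 / ratio)^(35 / 2))

  # arithmetic benchmark: M=36, p=1, variance ratio 2 -> F = 33, and the
  # F(1,33) upper tail there is far below 0.001 (independent tail oracle)
  expect_lt(pf(33, 1, 33, lower.tail = FALSE), 0.001)

  # perfect AR fit: zero AR variance forces p-value 0
  g <- 2^(0:35)
  ot0 <- f_test(fit_ar(g, 1), fit_constant(g, 1))
  expect_equal(ot0$p_value, 0)

  # response window constant but series testable: degenerate, p-value 1
  y <- c(5, rep(1, 9))
  otd <- f_test(fit_ar(y, 1), fit_constant(y, 1))
  expect_true(otd$degenerate)
  expect_equal(otd$p_value, 1)

  # mismatched fits are a contract error
  expect_error(f_test(fit_ar(x, 1), fit_constant(x, 2)), "different series or orders")
})

test_that("nesting and shift/scale invariance hold across random series", {
  set.seed(405)
  for (i in 1:25) {
    x <- rnorm(36, mean = 5, sd = 2)
    p <- sample.int(6L, 1)
    ar <- fit_ar(x, p); co <- fit_constant(x, p)
    expect_lte(ar$residual_variance, co$residual_variance + 1e-12)
    ot <- f_test(ar, co)
    expect_lte(ot$lambda_ratio, 1 + 1e-12)
    expect_gte(ot$f_stat, 0)

    # shift: beta0 moves, variances and F do not
    sh <- x + 11.5
    expect_equal(fit_constant(sh, p)$beta0, co$beta0 + 11.5)
    expect_equal(fit_ar(sh, p)$residual_variance, ar$residual_variance,
                 tolerance = 1e-8)
    expect_equal(f_test(fit_ar(sh, p), fit_constant(sh, p))$f_stat,
                 ot$f_stat, tolerance = 1e-6)

    # scale by c > 0: variances scale by c^2, F unchanged
    sc <- 3 * x
    expect_equal(fit_ar(sc, p)$residual_variance, 9 * ar$residual_variance,
                 tolerance = 1e-8)
    expect_equal(f_test(fit_ar(sc, p), fit_constant(sc, p))$f_stat,
                 ot$f_stat, tolerance = 1e-6)
  }
})

test_that("classify_profile applies the smallest-p-value-over-orders rule", {
  # constant series: degenerate, time-independent
  r <- classify_profile(rep(2, 36), p_max = 6, alpha = 0.01)
  expect_equal(r$label, "time_independent")
  expect_true(r$degenerate)

  # exact geometric AR(1): time-dependent at any alpha
  r2 <- classify_profile(2^(0:35), p_max = 6, alpha = 0.01)
  expect_equal(r2$label, "time_dependent")
  expect_equal(r2$min_p_value, 0)

  # p_max clipped so every tested order keeps positive denominator df
  r3 <- classify_profile(rnorm(8), p_max = 6)
  expect_lte(max(r3$per_order$order), 3)
  expect_error(classify_profile(c(1, 2, 1, 2), p_max = 2, alpha = 1.5))
})

test_that("single-order p-values are conservative-to-uniform under the iid null", {
  # The F(p, M-2p-1) reference is asymptotic for autoregressions. At
  # M=36 the test runs slightly conservative, so the empirical size must
  # not exceed the nominal level beyond Monte-Carlo error, and the
  # p-value distribution must approach uniformity as M grows.
  set.seed(406)
  n <- 2000
  pv <- vapply(seq_len(n), function(i) {
    x <- rnorm(36)
    f_test(fit_ar(x, 3), fit_constant(x, 3))$p_value
  }, numeric(1))
  for (a in c(0.01, 0.05, 0.1)) {
    se <- sqrt(a * (1 - a) / n)
    expect_lte(mean(pv < a), a + 3 * se)
  }
  # at M = 400 the same test is calibrated: KS cannot reject uniformity
  pv_long <- vapply(seq_len(500), function(i) {
    x <- rnorm(400)
    f_test(fit_ar(x, 3), fit_constant(x, 3))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pv_long, "punif")$p.value, 0.01)
})

test_that("multi-order screening respects the Bonferroni false-positive bound", {
  set.seed(407)
  n <- 1000
  labels <- vapply(seq_len(n), function(i)
    classify_profile(rnorm(36), p_max = 6, alpha = 0.01)$label, character(1))
  frac <- mean(labels == "time_dependent")
  se <- sqrt(0.06 * 0.94 / n)
  expect_lte(frac, 0.06 + 3 * se)
})

test_that("screen_matrix matches classify_profile and summarises a matrix", {
  set.seed(408)
  # all-constant matrix: nothing time-dependent
  m0 <- expr_matrix(replicate(10, rep(4, 36), simplify = FALSE))
  s0 <- screen_matrix(m0, quiet = TRUE)
  expect_equal(sum(s0$label == "time_dependent"), 0L)
  expect_true(all(s0$degenerate))

  # single-gene matrix agrees with classify_profile on that gene
  x <- rnorm(36)
  m1 <- expr_matrix(list(x))
  s1 <- screen_matrix(m1, quiet = TRUE)
  r1 <- classify_profile(x, gene_id = "g1")
  expect_equal(s1$min_p_value, r1$min_p_value)
  expect_equal(s1$label, r1$label)

  # power: AR(2)-generated genes are found, white noise mostly is not
  gen_ar2 <- function() {
    x <- numeric(56)
    for (m in 3:56) x[m] <- 0.9 * x[m - 1] - 0.3 * x[m - 2] + rnorm(1, 0, 0.3)
    5 + x[21:56]
  }
  m2 <- expr_matrix(c(replicate(20, gen_ar2(), simplify = FALSE),
                      replicate(80, rnorm(36, 5), simplify = FALSE)))
  s2 <- screen_matrix(m2, quiet = TRUE)
  expect_gte(sum(s2$label[1:20] == "time_dependent"), 18)
})
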