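test_that("the statistic is the oriented dot product with NA exclusion", {
  expect_equal(ghat_statistic(c(1, 2, 3), c(0, 0, 0)), 0)
  expect_equal(ghat_statistic(c(2, 1), c(0.1, -0.2)), 0)

  set.seed(51)
  a <- rnorm(1000); d <- rnorm(1000)
  brute <- 0
  for (j in seq_len(1000)) brute <- brute + a[j] * d[j]   # oracle loop
  expect_equal(ghat_statistic(a, d), brute)

  a[5] <- NA
  expect_equal(ghat_statistic(a, d), sum(a[-5] * d[-5]))
  expect_error(ghat_statistic(1:3, 1:2), "equal length")
  expect_error(ghat_statistic(NA_real_, 1), "missing")
})

test_that("a zero change vector gives a degenerate, non-significant test", {
  set.seed(52)
  expect_warning(res <- ghat_test(rnorm(200), rep(0, 200),
                                  method = "naive", perms = 200, seed = 1),
                 "degenerate")
  expect_equal(res$ghat_obs, 0)
  expect_gte(res$p_value, 0.99)
  expect_equal(res$direction, "none")
})

test_that("scale with num_eff = m reproduces the naive p exactly", {
  set.seed(53)
  a <- rnorm(400); d <- rnorm(400, sd = 0.1)
  r1 <- ghat_test(a, d, method = "scale", num_eff = 400, perms = 300,
                  seed = 7)
  r2 <- ghat_test(a, d, method = "naive", perms = 300, seed = 7)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$ghat_obs, r2$ghat_obs)
})

test_that("decreasing num_eff strictly increases the p-value", {
  set.seed(54)
  a <- rnorm(600); d <- rnorm(600, sd = 0.05) + 0.01 * a
  ps <- vapply(c(600, 300, 100, 20), function(ne)
    ghat_test(a, d, method = "scale", num_eff = ne, perms = 200,
              seed = 3)$p_value, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("negating delta negates Ghat and preserves the two-sided p", {
  set.seed(55)
  a <- rnorm(300); d <- rnorm(300, sd = 0.1)
  r1 <- ghat_test(a, d, method = "scale", num_eff = 200, perms = 200,
                  seed = 9)
  r2 <- ghat_test(a, -d, method = "scale", num_eff = 200, perms = 200,
                  seed = 9)
  expect_equal(r2$ghat_obs, -r1$ghat_obs)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("orientation flips leave the test invariant", {
  set.seed(56)
  a <- rnorm(300); d <- rnorm(300, sd = 0.1)
  r0 <- ghat_test(a, d, method = "scale", num_eff = 250, perms = 400,
                  seed = 4)
  # global flip: exactly invariant, including the permutation null
  rg <- ghat_test(-a, -d, method = "scale", num_eff = 250, perms = 400,
                  seed = 4)
  expect_equal(rg$ghat_obs, r0$ghat_obs)
  expect_equal(rg$p_value, r0$p_value)
  # partial flip: the statistic is exactly invariant; the permutation null
  # is redrawn over a slightly different multiset, so p agrees to
  # Monte-Carlo error
  flip <- sample(300, 40)
  a2 <- a; d2 <- d
  a2[flip] <- -a2[flip]; d2[flip] <- -d2[flip]
  rp <- ghat_test(a2, d2, method = "scale", num_eff = 250, perms = 400,
                  seed = 4)
  expect_equal(rp$ghat_obs, r0$ghat_obs)
  expect_lt(abs(rp$p_value - r0$p_value), 0.1)
})

test_that("jointly permuting alpha and delta leaves the test invariant", {
  set.seed(57)
  a <- rnorm(300); d <- rnorm(300, sd = 0.1)
  pi <- sample(300)
  r0 <- ghat_test(a, d, method = "naive", perms = 2000, seed = 8)
  r1 <- ghat_test(a[pi], d[pi], method = "naive", perms = 2000, seed = 8)
  expect_equal(r1$ghat_obs, r0$ghat_obs)
  expect_lt(abs(r1$p_value - r0$p_value), 0.1)
})

test_that("trim thins deterministically and respects its block size", {
  set.seed(58)
  a <- rnorm(500); d <- rnorm(500, sd = 0.1)
  r <- ghat_test(a, d, method = "trim", blocksize = 10, perms = 200,
                 seed = 2)
  expect_equal(r$m_used, 50)
  keep <- seq(1, 500, by = 10)
  expect_equal(r$ghat_obs, sum(a[keep] * d[keep]))
  expect_false(is.na(r$empirical_p))
  expect_error(ghat_test(a, d, method = "trim", perms = 200),
               "blocksize")
  expect_error(ghat_test(a, d, method = "scale", num_eff = 501,
                         perms = 200), "num_eff")
  expect_error(ghat_test(a, d, perms = 50, method = "naive"),
               "at least 100")
})

test_that("the back-calculated confidence interval matches the normal
           quantile oracle", {
  ci <- ci_from_pvalue(1, 2 * pnorm(-1), 0.95)   # p = 0.3173
  expect_equal(ci, c(1 - qnorm(0.975), 1 + qnorm(0.975)), tolerance = 1e-9)
  expect_equal(ci, c(-0.96, 2.96), tolerance = 0.01)

  # interval collapses around the estimate as p -> 0
  w <- diff(ci_from_pvalue(1, 1e-12, 0.95))
  expect_lt(w, 0.6)
  w2 <- diff(ci_from_pvalue(1, 1e-300, 0.95))
  expect_lt(w2, w)

  # symmetric under negation of the estimate
  expect_equal(ci_from_pvalue(-1, 0.3173, 0.95),
               -rev(ci_from_pvalue(1, 0.3173, 0.95)))

  expect_warning(ci0 <- ci_from_pvalue(0, 0.5), "undefined")
  expect_equal(ci0, c(-Inf, Inf))
  expect_warning(ci_from_pvalue(1, 1), "undefined")
})

test_that("the naive test is calibrated for independent markers", {
  set.seed(59)
  n_tests <- 800
  rej <- logical(n_tests)
  for (i in seq_len(n_tests)) {
    a <- rnorm(300)
    d <- rnorm(300, sd = 0.05)
    rej[i] <- ghat_test(a, d, method = "naive", perms = 150)$p_value < 0.01
  }
  # 99% binomial band around the nominal 1% level
  band <- qbinom(c(0.005, 0.995), n_tests, 0.01)
  expect_gte(sum(rej), band[1])
  expect_lte(sum(rej), band[2])
})

test_that("results are reproducible and self-describing", {
  set.seed(60)
  a <- rnorm(200); d <- rnorm(200, sd = 0.1)
  r1 <- ghat_test(a, d, method = "scale", num_eff = 150, perms = 200,
                  seed = 11)
  r2 <- ghat_test(a, d, method = "scale", num_eff = 150, perms = 200,
                  seed = 11)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_identical(r1$p_value, r2$p_value)
  expect_output(print(r1), "Ghat test")
  expect_output(print(summary(r1)), "permutation null")
  ci <- confint(r1, level = 0.99)
  expect_true(ci[1] < r1$ghat_obs, ci[2] > r1$ghat_obs)
})
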