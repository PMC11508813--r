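test_that("bland_altman recovers bias and limits of agreement", {
  set.seed(12)
  a <- runif(40, 1, 4)

  # constant offset: bias = -c, zero spread, flagged degenerate correlation
  rep1 <- bland_altman(a, a + 0.5)
  expect_equal(rep1$bias, -0.5)
  expect_equal(rep1$sd_diff, 0)
  expect_true(rep1$constant_diff)
  expect_equal(rep1$prop_bias_cor, 0)
  expect_equal(unname(rep1$loa), c(-0.5, -0.5))

  # identity: zero bias, degenerate LoA, perfect correlation
  rep2 <- bland_altman(a, a)
  expect_equal(rep2$bias, 0)
  expect_equal(unname(rep2$loa), c(0, 0))
  expect_equal(rep2$pearson_rho, 1)

  # random paired data against a direct arithmetic oracle
  b <- a + rnorm(40, 0.2, 0.3)
  rep3 <- bland_altman(a, b)
  d <- a - b
  expect_equal(rep3$bias, mean(d))
  expect_equal(rep3$sd_diff, sd(d))
  expect_equal(unname(rep3$loa),
               c(mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d)))
  expect_equal(rep3$pearson_rho, cor(a, b))
  expect_equal(rep3$prop_bias_cor, cor(d, (a + b) / 2))

  # antisymmetry of the bias
  expect_equal(bland_altman(b, a)$bias, -rep3$bias)

  expect_error(bland_altman(a, a[-1]), "length")
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("paired Wilcoxon matches exact sign enumeration for n <= 10", {
  set.seed(61)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    res <- paired_wilcoxon(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_wilcoxon(a - b), tolerance = 1e-12)
  }
})

test_that("paired Wilcoxon handles edge cases and large samples", {
  # uniformly positive differences, n = 20: overwhelming evidence
  a <- 1:20 + 0.5
  b <- 1:20
  res <- paired_wilcoxon(a, b)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$statistic, 20 * 21 / 2)

  # paired symmetric differences: statistic at the null center
  d <- c(1.3, -1.3, 0.7, -0.7, 2.1, -2.1, 0.2, -0.2)
  res2 <- paired_wilcoxon(d, numeric(8))
  expect_equal(res2$statistic, 8 * 9 / 4)

  # zero differences dropped; all-zero is degenerate
  res3 <- paired_wilcoxon(c(0, 0, 1, 2, -1), c(0, 0, 0, 0, 0))
  expect_equal(res3$n, 3)
  expect_error(paired_wilcoxon(1:4, 1:4), "degenerate")

  # ties or n > 25 route through the tie-corrected normal approximation,
  # which should stay close to the exact path on tie-free data
  set.seed(3)
  x <- rnorm(40)
  y <- x + rnorm(40, 0.1)
  res4 <- paired_wilcoxon(x, y)
  expect_false(res4$exact)
  expect_true(res4$p_value > 0 && res4$p_value <= 1)
})

test_that("ECDF curves superimpose after the bias shift", {
  set.seed(19)
  # dyadic values keep the constant shift exact in floating point, so the
  # superposition is bit-exact rather than approximate
  a <- sample(64:512, 60, replace = TRUE) / 16
  tab <- data.frame(ref = a, same = a, shifted = a - 0.75)
  res <- ecdf_bias_shift(tab, "ref")
  expect_equal(res$same$D_before, 0)
  expect_equal(res$same$D_after, 0)
  expect_gt(res$shifted$D_before, 0)
  expect_equal(res$shifted$bias, 0.75)
  expect_equal(res$shifted$D_after, 0)
  a <- rnorm(60, 5)
  # random location-shifted noisy samples: the shift never hurts
  for (i in 1:5) {
    b <- a + rnorm(60, sd = 0.05) + runif(1, -1, 1)
    r <- ecdf_bias_shift(data.frame(ref = a, m = b), "ref")
    expect_lte(r$m$D_after, r$m$D_before)
  }
  expect_error(ecdf_bias_shift(tab, "nope"), "reference")
})

test_that("cumulative mean converges across shuffles", {
  # constant vector: flat curve, zero SE
  res <- cumulative_mean_convergence(rep(2.5, 30), seed = 7)
  expect_true(all(res$mean_curve == 2.5))
  expect_true(all(res$se_curve == 0))

  set.seed(2)
  v <- rexp(50)
  res2 <- cumulative_mean_convergence(v, n_shuffles = 15, seed = 7)
  expect_equal(dim(res2$curves), c(15, 50))
  # the final cumulative mean equals the sample mean for every shuffle
  expect_true(all(abs(res2$curves[, 50] - mean(v)) < 1e-12))
  # SE decay follows sd/sqrt(k)
  expect_equal(res2$se_curve[1] / res2$se_curve[25], sqrt(25))
  # reproducible under the seed
  res3 <- cumulative_mean_convergence(v, n_shuffles = 15, seed = 7)
  expect_identical(res2$curves, res3$curves)
})

test_that("deviation_study summarizes absolute percentage deviations", {
  tab <- data.frame(Expected = c(1, 2, 4), AIS = c(1, 2, 4),
                    MA1 = c(1.1, 2.2, 4.4))
  res <- deviation_study(tab, "Expected", group = "regular")
  expect_equal(res$mean_pct[res$method == "AIS"], 0)
  expect_equal(res$mean_pct[res$method == "MA1"], 10, tolerance = 1e-12)
  expect_equal(res$n, c(3L, 3L))
  # scale invariance
  res10 <- deviation_study(tab * 10, "Expected")
  expect_equal(res10$mean_pct, res$mean_pct)
  expect_equal(res10$max_pct, res$max_pct)
  expect_error(deviation_study(tab, "Corel"), "reference")
})
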