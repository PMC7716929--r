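test_that("Wilson interval matches closed forms and the score-test oracle", {
  # x = 0: lower 0, upper z^2/(n + z^2)
  z2 <- qnorm(0.975)^2
  ci0 <- wilson_ci(0, 10)
  expect_equal(unname(ci0), c(0, z2 / (10 + z2)), tolerance = 1e-10)
  expect_equal(unname(ci0[2]), 0.2775, tolerance = 5e-4)
  # x = n mirrors the x = 0 case
  cin <- wilson_ci(10, 10)
  expect_equal(unname(cin), c(1 - z2 / (10 + z2), 1), tolerance = 1e-10)
  expect_equal(unname(wilson_ci(5, 10)), c(0.2366, 0.7634), tolerance = 5e-5)
  # independent oracle: score interval from prop.test without correction
  for (xn in list(c(3, 17), c(40, 100), c(0, 8), c(250, 260))) {
    ref <- suppressWarnings(prop.test(xn[1], xn[2], correct = FALSE))$conf.int
    expect_equal(unname(wilson_ci(xn[1], xn[2])), as.numeric(ref),
                 tolerance = 1e-9)
  }
  expect_error(wilson_ci(5, 0), "positive")
  expect_error(wilson_ci(11, 10), "\\[0, n\\]")
  # bounds in [0,1] and containing x/n, over a grid
  for (n in c(1, 7, 100)) for (x in unique(c(0, 1, n))) {
    ci <- wilson_ci(x, n)
    expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= x / n && x / n <= ci[2])
  }
})

test_that("Newcombe interval reproduces the trial's published attendance rows", {
  # overall attendance, per protocol
  ov <- newcombe_diff_ci(1754, 2097, 1883, 2224)
  expect_equal(round(ov$D, 3), -0.010)
  expect_equal(round(ov$lower, 3), -0.032)
  expect_equal(round(ov$upper, 3), 0.012)
  # low-risk STDR row
  lr <- newcombe_diff_ci(4, 1650, 10, 1709)
  expect_equal(round(lr$lower, 3), -0.009)
  expect_equal(round(lr$upper, 3), 0.001)
  # STDR overall
  sd <- newcombe_diff_ci(28, 1956, 35, 2042)
  expect_equal(round(sd$D, 3), -0.003)
  expect_equal(round(sd$lower, 3), -0.011)
  expect_equal(round(sd$upper, 3), 0.005)
})

test_that("Newcombe interval contains D, and is anti-symmetric in the arms", {
  set.seed(161)
  for (i in 1:20) {
    n1 <- sample(5:300, 1); n2 <- sample(5:300, 1)
    x1 <- rbinom(1, n1, runif(1)); x2 <- rbinom(1, n2, runif(1))
    a <- newcombe_diff_ci(x1, n1, x2, n2)
    b <- newcombe_diff_ci(x2, n2, x1, n1)
    expect_lte(a$lower, a$D); expect_gte(a$upper, a$D)
    expect_equal(a$lower, -b$upper, tolerance = 1e-12)
    expect_equal(a$upper, -b$lower, tolerance = 1e-12)
  }
  eq <- newcombe_diff_ci(30, 100, 30, 100)
  expect_equal(eq$D, 0)
  expect_equal(eq$lower, -eq$upper, tolerance = 1e-12)
})

test_that("equivalence and non-inferiority verdicts follow the margins strictly", {
  expect_equal(equivalence_verdict(c(-0.032, 0.012)), "equivalent")
  expect_equal(equivalence_verdict(c(-0.136, 0.035)), "not-established")
  expect_equal(equivalence_verdict(c(-0.05, 0.05)), "not-established")  # boundary
  expect_equal(equivalence_verdict(c(-0.05, 0.05), strict = FALSE), "equivalent")
  expect_equal(noninferiority_verdict(c(-0.011, 0.005)), "non-inferior")
  expect_equal(noninferiority_verdict(c(-0.009, 0.001)), "non-inferior")
  expect_equal(noninferiority_verdict(c(-0.020, 0.001)), "not-established")
  # enlarging the margin never flips equivalent -> not-established
  set.seed(162)
  for (i in 1:30) {
    ci <- sort(runif(2, -0.2, 0.2))
    m1 <- runif(1, 0.01, 0.1); m2 <- m1 + runif(1, 0, 0.1)
    if (equivalence_verdict(ci, m1) == "equivalent")
      expect_equal(equivalence_verdict(ci, m2), "equivalent")
    if (noninferiority_verdict(ci, m1) == "non-inferior")
      expect_equal(noninferiority_verdict(ci, m2), "non-inferior")
  }
})

test_that("Newcombe 95% interval coverage is near nominal across scenarios", {
  set.seed(163)
  n <- 200
  for (p in c(0.05, 0.5, 0.85)) {
    x1 <- rbinom(2000, n, p); x2 <- rbinom(2000, n, p)
    covered <- mapply(function(a, b) {
      ci <- newcombe_diff_ci(a, n, b, n)
      ci$lower <= 0 && 0 <= ci$upper
    }, x1, x2)
    expect_gte(mean(covered), 0.93)
  }
})

test_that("subgroup analysis matches direct 2x2 intervals and the saturated GLM identity", {
  set.seed(164)
  d <- data.frame(
    arm = rep(c("control", "individualised"), each = 300),
    group0 = sample(c("high", "medium", "low"), 600, TRUE),
    outcome = runif(600) < 0.8
  )
  res <- subgroup_analysis(d)
  for (g in c("high", "medium", "low")) {
    dg <- d[d$group0 == g, ]
    ref <- newcombe_diff_ci(sum(dg$outcome[dg$arm == "individualised"]),
                            sum(dg$arm == "individualised"),
                            sum(dg$outcome[dg$arm == "control"]),
                            sum(dg$arm == "control"))
    row <- res$by_group[res$by_group$group == g, ]
    expect_equal(row$D, ref$D)
    expect_equal(row$lower, ref$lower)
    expect_equal(row$upper, ref$upper)
  }
  # saturated model reproduces the observed per-cell proportions exactly
  pred <- predict(res$glm, type = "response")
  cells <- interaction(d$arm, d$group0)
  obs <- tapply(d$outcome, cells, mean)
  expect_equal(unname(tapply(pred, cells, mean)), unname(obs), tolerance = 1e-9)
  # identical rates across arms give interaction terms near zero
  d2 <- d; d2$outcome <- rep(rep(c(TRUE, FALSE), c(8, 2)), 60)
  res2 <- subgroup_analysis(d2)
  ints <- grep(":", rownames(res2$wald))
  expect_true(all(abs(res2$wald[ints, "Estimate"]) < 1))
})

test_that("Rubin pooling reproduces hand arithmetic and degenerates correctly", {
  pooled <- rubin_pool(c(0.1, 0.2, 0.3), c(0.01, 0.01, 0.01))
  expect_equal(pooled$estimate, 0.2)
  expect_equal(pooled$variance, 0.01 + (1 + 1 / 3) * 0.01, tolerance = 1e-12)
  expect_equal(pooled$within, 0.01)
  expect_equal(pooled$between, 0.01)
  expect_error(rubin_pool(0.1, 0.01), "at least 2")
  # B = 0: pooled equals the common single-set result, normal reference
  same <- rubin_pool(rep(0.25, 5), rep(0.004, 5))
  expect_equal(same$estimate, 0.25)
  expect_equal(same$between, 0)
  expect_equal(same$variance, 0.004)
  expect_equal(same$df, Inf)
})

test_that("imputation leaves complete data untouched and is unbiased under MCAR", {
  d <- data.frame(outcome = c(TRUE, FALSE, TRUE), age = c(50, 60, 70))
  imp <- impute_missing(d, "age", m = 3, seed = 171)
  expect_identical(imp[[1]], d)
  expect_identical(imp[[2]], d)

  # MCAR simulation: pooled attendance difference unbiased
  set.seed(172)
  reps <- 200
  bias <- vapply(seq_len(reps), function(r) {
    n <- 250
    d <- data.frame(arm = rep(c("control", "individualised"), each = n),
                    age = rnorm(2 * n, 60, 10))
    p <- ifelse(d$arm == "control", 0.85, 0.80)
    d$outcome <- runif(2 * n) < p
    d$outcome[runif(2 * n) < 0.10] <- NA
    imp <- impute_missing(d, "age", m = 5, seed = 1000 + r)
    ests <- vapply(imp, function(di) {
      mean(di$outcome[di$arm == "individualised"]) -
        mean(di$outcome[di$arm == "control"])
    }, numeric(1))
    vars <- vapply(imp, function(di) {
      p1 <- mean(di$outcome[di$arm == "individualised"])
      p2 <- mean(di$outcome[di$arm == "control"])
      p1 * (1 - p1) / n + p2 * (1 - p2) / n
    }, numeric(1))
    rubin_pool(ests, vars)$estimate - (-0.05)
  }, numeric(1))
  mc_se <- sd(bias) / sqrt(reps)
  expect_lt(abs(mean(bias)), 2 * mc_se + 0.002)
})

test_that("simple imputation fill rules act deterministically", {
  d <- data.frame(outcome = c(TRUE, NA, FALSE, NA))
  expect_equal(simple_impute(d, "all-attended")$outcome, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(simple_impute(d, "none-attended")$outcome, c(TRUE, FALSE, FALSE, FALSE))
})
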