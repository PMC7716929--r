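test_that("per-participant costs follow the unit-cost arithmetic exactly", {
  expect_equal(participant_costs(2, 1),
               c(nhs = 70.19, societal = 88.19))
  expect_equal(participant_costs(0, 0), c(nhs = 0, societal = 0))
  expect_equal(participant_costs(0, 1), c(nhs = 12.73, societal = 12.73))
})

test_that("QALY area under the curve handles constants, declines and horizons", {
  expect_equal(qaly_auc(c(0, 24), c(1, 1)), 2)
  expect_equal(qaly_auc(c(0, 24), c(0, 0)), 0)
  expect_equal(qaly_auc(c(0, 24), c(1, 0)), 1)  # triangle
  # flat extrapolation when the series ends early
  expect_equal(qaly_auc(c(0, 12), c(1, 0.5), horizon = 24),
               (0.75 + 0.5) * 1)
  # truncation past the horizon interpolates the crossing segment
  expect_equal(qaly_auc(c(0, 30), c(1, 0), horizon = 24),
               (1 + 0.2) / 2 * 2)
  expect_error(qaly_auc(0, 1), "two utility")
  expect_error(qaly_auc(c(3, 24), c(1, 1)), "baseline")
})

test_that("bias-corrected interval reduces to percentile when median-centred", {
  set.seed(181)
  draws <- rnorm(4000, 0.05, 0.01)
  est <- median(draws)  # forces z0 = 0 up to quantisation
  bc <- bc_interval(draws, est)
  pc <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 6)
  expect_equal(unname(bc), pc, tolerance = 2e-4)
  expect_error(bc_interval(0.1, 0.1), "at least 2")
})

test_that("identical arms give zero incremental effects with CIs containing zero", {
  d <- data.frame(arm = rep(c("control", "individualised"), each = 50),
                  qaly = rep(1.5, 100), cost = rep(70.19, 100),
                  baseline_utility = rep(0.9, 100))
  res <- incremental_cea(d, iterations = 50, seed = 191)
  expect_equal(unname(res$inc_qaly["estimate"]), 0, tolerance = 1e-10)
  expect_equal(unname(res$inc_cost["estimate"]), 0, tolerance = 1e-10)
  expect_true(res$inc_qaly["lower"] <= 1e-10 && res$inc_qaly["upper"] >= -1e-10)
  expect_true(res$inc_cost["lower"] <= 1e-10 && res$inc_cost["upper"] >= -1e-10)
  expect_equal(nrow(res$draws), 50)
})

test_that("a noiseless injected cost difference is recovered exactly", {
  d <- data.frame(arm = rep(c("control", "individualised"), each = 40),
                  qaly = rep(1.8, 80),
                  cost = rep(c(100, 100 - 17.34), each = 40),
                  baseline_utility = rep(0.85, 80))
  res <- incremental_cea(d, iterations = 20, seed = 201)
  expect_equal(unname(res$inc_cost["estimate"]), -17.34, tolerance = 1e-10)
  # degenerate bootstrap: every resample reproduces the point estimate
  expect_equal(unname(res$inc_cost["lower"]), -17.34, tolerance = 1e-10)
  expect_equal(unname(res$inc_cost["upper"]), -17.34, tolerance = 1e-10)
})

test_that("SUR reduces to OLS with identical regressors and pools via Rubin", {
  set.seed(211)
  n <- 200
  arm <- rep(0:1, each = n / 2)
  X <- cbind(1, arm)
  y1 <- 1 + 0.05 * arm + rnorm(n, 0, 0.2)
  y2 <- 60 - 17 * arm + rnorm(n, 0, 5)
  s <- sur_fit(y1, X, y2, X)
  ols1 <- coef(lm(y1 ~ arm)); ols2 <- coef(lm(y2 ~ arm))
  expect_equal(unname(s$coef1), unname(ols1), tolerance = 1e-8)
  expect_equal(unname(s$coef2), unname(ols2), tolerance = 1e-8)

  # pooled CEA across identical sets equals the single-set SUR result
  d <- data.frame(arm = ifelse(arm == 1, "individualised", "control"),
                  qaly = y1, cost = y2, baseline_utility = rnorm(n, 0.9, 0.05))
  pooled <- pooled_cea(list(d, d, d), adjust = "unadjusted")
  expect_equal(pooled$inc_qaly$estimate, unname(ols1[2]), tolerance = 1e-8)
  expect_equal(pooled$inc_cost$estimate, unname(ols2[2]), tolerance = 1e-8)
  expect_equal(pooled$inc_qaly$between, 0)

  # Rubin arithmetic shared with the safety module
  m <- rbind(c(0.1, 0.01), c(0.2, 0.01), c(0.3, 0.01))
  expect_equal(rubin_pool(m[, 1], m[, 2])$variance, 0.01 + (4 / 3) * 0.01)
})

test_that("programme summary reproduces the published totals arithmetic", {
  # synthetic ledger forcing the published appointment counts
  fake <- list(
    participants = data.frame(id = 1:2, arm = c("control", "individualised")),
    visits = data.frame(
      id = rep(1:2, c(3536 + 600, 2008 + 400)),
      attended = c(rep(TRUE, 3536), rep(FALSE, 600),
                   rep(TRUE, 2008), rep(FALSE, 400)))
  )
  ps <- programme_summary(fake)
  expect_equal(ps$appointment_reduction_pct, 43.2)
  ctrl_nhs <- 3536 * 28.73 + 600 * 12.73
  ind_nhs <- 2008 * 28.73 + 400 * 12.73
  expect_equal(ps$by_arm$nhs_total, c(ctrl_nhs, ind_nhs))
  expect_equal(ps$nhs_reduction_pct, round(100 * (ctrl_nhs - ind_nhs) / ctrl_nhs))
  # equal totals: zero percent reduction
  fake2 <- list(participants = data.frame(id = 1:2, arm = c("control", "individualised")),
                visits = data.frame(id = rep(1:2, each = 10),
                                    attended = rep(TRUE, 20)))
  expect_equal(programme_summary(fake2)$nhs_reduction_pct, 0)
})

test_that("synthetic utility series feed the QALY pipeline end to end", {
  co <- generate_baseline_cohort(40, seed = 221)
  asg <- randomise(co, seed = 222)
  tr <- run_trial(co, asg, rce = default_progression_model(), seed = 223)
  us <- generate_utility_series(tr, instruments = "eq5d", seed = 224)
  expect_true(all(us$utility <= 1))
  expect_true(all(us$time_months[us$time_months == 0] == 0))
  one <- us[us$id == us$id[1], ]
  if (nrow(one) >= 2) {
    q <- qaly_auc(one$time_months, one$utility, horizon = 24)
    expect_true(q <= 2 && q >= -0.72)
  }
})
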