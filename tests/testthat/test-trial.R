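null_model <- function() default_progression_model(beta_scale = 0)

zero_model <- function() {
  multistate_model(rbind(c("R0R0", "SP")), log_q0 = -Inf)
}

full_attendance_profile <- function() {
  cohort_profile(attendance = rbind(control = c(high = 1, medium = 1, low = 1),
                                    individualised = c(high = 1, medium = 1, low = 1)),
                 withdrawal_annual = 0)
}

test_that("permuted-block randomisation balances within strata and is seeded", {
  co <- data.frame(id = 1:4, clinic = 1, age = rep(50, 4))
  a <- randomise(co, block_sizes_adult = 4, seed = 101)
  expect_equal(sum(a$arm == "control"), 2)
  expect_identical(a, randomise(co, block_sizes_adult = 4, seed = 101))

  co2 <- generate_baseline_cohort(1e4, seed = 102)
  a2 <- randomise(co2, seed = 103)
  # worst-case prefix imbalance: half the largest block per stratum
  n_strata <- length(unique(a2$stratum))
  expect_lte(abs(sum(a2$arm == "control") - sum(a2$arm == "individualised")),
             n_strata * 3)
  for (s in unique(a2$stratum)) {
    arms <- a2$arm[a2$stratum == s]
    expect_lte(abs(sum(arms == "control") - sum(arms == "individualised")), 3)
  }
  expect_error(randomise(data.frame(id = 1, clinic = NA, age = 50)), "stratum")
})

test_that("a null-progression trial with full attendance has fixed schedules", {
  co <- generate_baseline_cohort(60, seed = 111)
  co$state0 <- "R0R0"; co$prior_ret <- 0L
  asg <- randomise(co, seed = 112)
  tr <- run_trial(co, asg, rce = null_model(), truth = zero_model(),
                  profile = full_attendance_profile(), seed = 113)
  v <- tr$visits; p <- tr$participants
  # control arm: exactly two follow-ups at 12 and 24 months, no events
  ctrl_ids <- p$id[p$arm == "control"]
  for (i in ctrl_ids) {
    expect_equal(v$invitation[v$id == i], c(12, 24))
  }
  expect_true(all(!v$screen_positive))
  expect_true(all(!p$stdr))
  # all low risk under the null RCE: individualised arm has exactly 1 visit,
  # so the appointment reduction approaches 50%
  ind_ids <- p$id[p$arm == "individualised"]
  expect_true(all(p$group0[p$arm == "individualised"] == "low"))
  for (i in ind_ids) expect_equal(v$invitation[v$id == i], 24)
  per_ctrl <- sum(v$id %in% ctrl_ids) / length(ctrl_ids)
  per_ind <- sum(v$id %in% ind_ids) / length(ind_ids)
  expect_equal(1 - per_ind / per_ctrl, 0.5)
})

test_that("invitation accounting conserves participants and respects withdrawal", {
  co <- generate_baseline_cohort(400, seed = 121)
  asg <- randomise(co, seed = 122)
  pr <- cohort_profile(withdrawal_annual = 0.10)
  tr <- run_trial(co, asg, rce = default_progression_model(),
                  profile = pr, seed = 123)
  p <- tr$participants; v <- tr$visits
  # every invitation is attended or missed; no visits after withdrawal
  expect_true(all(v$attended %in% c(TRUE, FALSE)))
  for (i in p$id[!is.na(p$withdrawal_time)]) {
    wd <- p$withdrawal_time[p$id == i]
    expect_true(all(v$invitation[v$id == i] < wd))
  }
  # confirmed STDR participants exit routine recall
  for (i in p$id[p$stdr]) {
    vi <- v[v$id == i, ]
    k <- which(vi$stdr_confirmed)
    expect_equal(k, nrow(vi))
  }
  # control-arm invitation times are 12-month multiples
  ctrl <- v[v$id %in% p$id[p$arm == "control"], ]
  expect_true(all(ctrl$invitation %in% c(12, 24)))
  # analysis-set partition: attended + not attended = kept, per arm
  sets <- build_analysis_sets(tr)
  cnt <- sets$attendance$pp$counts
  d <- sets$attendance$pp$data
  for (a in c("control", "individualised")) {
    n_a <- cnt$n[cnt$group == "overall" & cnt$arm == a]
    expect_equal(n_a, sum(d$arm == a))
    expect_equal(cnt$x[cnt$group == "overall" & cnt$arm == a],
                 sum(d$outcome[d$arm == a]))
    expect_equal(sum(cnt$n[cnt$group != "overall" & cnt$arm == a]), n_a)
  }
  # ITT keeps everyone randomised; PP is a subset
  expect_equal(nrow(sets$attendance$itt$data), nrow(p))
  expect_lte(nrow(sets$attendance$pp$data), nrow(p))
})

test_that("without deviations or withdrawals the analysis sets coincide", {
  co <- generate_baseline_cohort(150, seed = 131)
  asg <- randomise(co, seed = 132)
  tr <- run_trial(co, asg, rce = default_progression_model(),
                  profile = full_attendance_profile(), seed = 133)
  sets <- build_analysis_sets(tr)
  expect_equal(sets$attendance$pp$counts, sets$attendance$itt$counts)
})

test_that("injected protocol deviations shrink the per-protocol set only", {
  co <- generate_baseline_cohort(300, seed = 141)
  asg <- randomise(co, seed = 142)
  tr <- run_trial(co, asg, rce = default_progression_model(),
                  profile = full_attendance_profile(),
                  config = trial_config(deviation_rate = 0.2), seed = 143)
  sets <- build_analysis_sets(tr)
  n_dev <- sum(tr$participants$deviated)
  expect_gt(n_dev, 0)
  expect_equal(nrow(sets$attendance$itt$data) - nrow(sets$attendance$pp$data),
               n_dev)
})

test_that("an A/A configuration yields a null arm difference in attendance", {
  # same attendance probabilities in both arms, null truth model
  pr <- cohort_profile(attendance = rbind(control = c(high = .8, medium = .8, low = .8),
                                          individualised = c(high = .8, medium = .8, low = .8)),
                       withdrawal_annual = 0)
  diffs <- vapply(1:20, function(r) {
    co <- generate_baseline_cohort(400, seed = 1500 + r)
    asg <- randomise(co, seed = 1600 + r)
    tr <- run_trial(co, asg, rce = default_progression_model(beta_scale = 0),
                    truth = zero_model(), profile = pr, seed = 1700 + r)
    d <- counts_to_diff(build_analysis_sets(tr)$attendance$pp$counts[1:2, ])
    d$x1 / d$n1 - d$x2 / d$n2
  }, numeric(1))
  se <- sqrt(0.8 * 0.2 * 2 / 400) / sqrt(20)
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("trial simulation is reproducible under a fixed seed", {
  co <- generate_baseline_cohort(100, seed = 151)
  asg <- randomise(co, seed = 152)
  t1 <- run_trial(co, asg, rce = default_progression_model(), seed = 153)
  t2 <- run_trial(co, asg, rce = default_progression_model(), seed = 153)
  expect_identical(t1$visits, t2$visits)
  expect_identical(t1$participants, t2$participants)
})
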