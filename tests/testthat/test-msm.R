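test_that("intensity matrix matches the log-linear formula and generator laws", {
  tr <- rbind(c("R0R0", "R1R0"), c("R1R0", "SP"))
  beta <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2,
                 dimnames = list(NULL, c("a", "b")))
  m <- multistate_model(tr, log_q0 = c(-3, -4), beta = beta,
                        centers = c(a = 1, b = 2),
                        states = c("R0R0", "R1R0", "SP"))
  z <- list(a = 2.5, b = 1.0)
  Q <- intensity_matrix(m, z)
  # hand evaluation of exp(log q0 + beta . (z - centre))
  expect_equal(Q["R0R0", "R1R0"], exp(-3 + 0.5 * 1.5 + 0.1 * (-1)))
  expect_equal(Q["R1R0", "SP"], exp(-4 - 0.2 * 1.5 + 0.3 * (-1)))
  expect_equal(unname(rowSums(Q)), c(0, 0, 0))
  expect_true(all(Q["SP", ] == 0))
  # null covariate effect: doubling the covariate changes nothing
  m0 <- multistate_model(tr, log_q0 = c(-3, -4),
                         beta = matrix(0, 2, 2, dimnames = list(NULL, c("a", "b"))),
                         centers = c(a = 0, b = 0),
                         states = c("R0R0", "R1R0", "SP"))
  expect_equal(intensity_matrix(m0, list(a = 1, b = 1)),
               intensity_matrix(m0, list(a = 2, b = 2)))
  expect_error(intensity_matrix(m, list(a = NA, b = 1)), "covariate")
})

test_that("transition probabilities obey CTMC semantics", {
  # t = 0 gives the identity
  m <- toy_model()
  Q <- intensity_matrix(m)
  expect_equal(unname(transition_probabilities(Q, 0)), diag(3), tolerance = 1e-12)
  # two-state closed form: P[1,2](t) = 1 - exp(-q t)
  m2 <- single_exit_model(q = 0.1)
  P <- transition_probabilities(intensity_matrix(m2), 12)
  expect_equal(P["R1R1", "SP"], 1 - exp(-1.2), tolerance = 1e-10)
  expect_error(transition_probabilities(Q, -1), "non-negative")
})

test_that("Chapman-Kolmogorov and row-stochasticity hold for random generators", {
  for (s in 1:5) {
    m <- random_valid_model(100 + s)
    Q <- intensity_matrix(m)
    t <- runif(1, 1, 24)
    P1 <- transition_probabilities(Q, t)
    P2 <- transition_probabilities(Q, 2 * t)
    expect_lt(max(abs(P2 - P1 %*% P1)), 1e-8)
    expect_equal(unname(rowSums(P1)), rep(1, 4), tolerance = 1e-10)
    expect_true(all(P1 >= 0 & P1 <= 1))
  }
})

test_that("screen-positive risk has closed form and is monotone in horizon", {
  m2 <- single_exit_model(q = 0.01)
  expect_equal(screen_positive_risk(m2, "R1R1", horizon = 12),
               1 - exp(-0.12), tolerance = 1e-10)
  expect_equal(screen_positive_risk(m2, "R1R1", horizon = 0), 0)
  expect_error(screen_positive_risk(m2, "SP", horizon = 12), "absorbing")
  for (s in 1:5) {
    m <- random_valid_model(200 + s)
    for (st in c("R0R0", "R1R0", "R1R1")) {
      rp <- risk_profile(m, st)
      expect_true(rp["risk6"] <= rp["risk12"] + 1e-12 &&
                    rp["risk12"] <= rp["risk24"] + 1e-12)
    }
  }
})

test_that("interval allocation follows the threshold cascade", {
  expect_equal(allocate_interval(c(0.001, 0.002, 0.004))$interval, 24)
  expect_equal(allocate_interval(c(0.001, 0.010, 0.030))$interval, 12)
  expect_equal(allocate_interval(c(0.030, 0.040, 0.060))$interval, 6)
  # a risk exactly at the threshold does not qualify for the longer interval
  expect_equal(allocate_interval(c(0.01, 0.02, 0.025))$group, "medium")
  expect_equal(allocate_interval(c(0.01, 0.025, 0.030))$group, "high")
})

test_that("allocation is monotone in the threshold", {
  set.seed(7)
  for (i in 1:50) {
    rp <- sort(runif(3, 0, 0.2))
    taus <- sort(runif(2, 0.001, 0.15))
    i1 <- allocate_interval(rp, taus[1])$interval
    i2 <- allocate_interval(rp, taus[2])$interval
    expect_gte(i2, i1)  # larger threshold never shortens the interval
  }
})

test_that("two-screen stratification rule allocates 24 months only for double R0R0", {
  expect_equal(simple_stratification(c("R0R0", "R0R0")), 24)
  expect_equal(simple_stratification(c("R0R0", "R1R0")), 12)
  expect_equal(simple_stratification(c("R1R1", "R1R1")), 12)
  expect_equal(simple_stratification("R0R0"), 24)
})

test_that("model construction rejects invalid structures", {
  expect_error(multistate_model(rbind(c("SP", "R0R0")), log_q0 = -1),
               "absorbing")
  expect_error(multistate_model(rbind(c("R0R0", "R0R0")), log_q0 = -1),
               "self-transitions")
  expect_error(multistate_model(rbind(c("R0R0", "R1R0")), log_q0 = c(-1, -2)),
               "one baseline")
})
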