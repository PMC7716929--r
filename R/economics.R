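#' Screening-programme cost schedule
#'
#' Unit costs (GBP, 2019/2020 values): the health-service cost of an
#' attended and of a missed screening appointment, and the additional
#' societal cost per attendance (participant/companion productivity losses
#' and out-of-pocket payments).
#'
#' @param nhs_per_attendance,nhs_per_nonattendance,societal_addon_per_attendance
#'   unit costs in GBP.
#' @return List of class \code{cost_schedule}.
#' @export
cost_schedule <- function(nhs_per_attendance = 28.73,
                          nhs_per_nonattendance = 12.73,
                          societal_addon_per_attendance = 9.00) {
  stopifnot(nhs_per_attendance >= 0, nhs_per_nonattendance >= 0,
            societal_addon_per_attendance >= 0)
  structure(list(nhs_per_attendance = nhs_per_attendance,
                 nhs_per_nonattendance = nhs_per_nonattendance,
                 societal_addon_per_attendance = societal_addon_per_attendance),
            class = "cost_schedule")
}

#' Per-participant screening costs
#'
#' NHS cost = attended x unit attendance cost + missed x unit
#' non-attendance cost; societal cost adds the societal add-on per
#' attendance. Exact decimal arithmetic at 2 decimal places.
#'
#' @param attended,missed appointment counts.
#' @param cs a \code{\link{cost_schedule}}.
#' @return Named vector \code{c(nhs, societal)} in GBP.
#' @export
participant_costs <- function(attended, missed, cs = cost_schedule()) {
  nhs <- round(attended * cs$nhs_per_attendance +
                 missed * cs$nhs_per_nonattendance, 2)
  c(nhs = nhs,
    societal = round(nhs + attended * cs$societal_addon_per_attendance, 2))
}

#' QALYs by area under the utility curve
#'
#' Trapezoidal area under the linearly interpolated utility index, time
#' converted from months to years. The series is truncated at the horizon
#' (linear interpolation of the crossing segment) and, when it ends before
#' the horizon, extrapolated flat at the last observed utility.
#'
#' @param times measurement times in months (non-decreasing, starting at 0).
#' @param utilities utility index at each time (<= 1; negative permitted).
#' @param horizon horizon in months (default 24).
#' @return QALYs over the horizon.
#' @export
qaly_auc <- function(times, utilities, horizon = 24) {
  stopifnot(length(times) == length(utilities))
  if (length(times) < 2) stop("at least two utility measurements are required")
  if (is.unsorted(times)) stop("times must be non-decreasing")
  if (times[1] != 0) stop("the first measurement must be at baseline (time 0)")
  if (max(times) < horizon) {           # flat extrapolation to horizon
    times <- c(times, horizon)
    utilities <- c(utilities, utilities[length(utilities)])
  }
  if (max(times) > horizon) {           # truncate at horizon
    u_h <- stats::approx(times, utilities, xout = horizon)$y
    keep <- times < horizon
    times <- c(times[keep], horizon)
    utilities <- c(utilities[keep], u_h)
  }
  sum(diff(times) * (utilities[-1] + utilities[-length(utilities)]) / 2) / 12
}

#' @keywords internal
#' OLS arm effect: outcome ~ arm (+ baseline), returning the arm coefficient.
.arm_effect <- function(outcome, arm, baseline = NULL) {
  X <- cbind(1, arm == "individualised")
  if (!is.null(baseline)) X <- cbind(X, baseline)
  # lm.fit keeps aliased columns NA in input order (safe under collinearity)
  unname(stats::lm.fit(X, outcome)$coefficients[2])
}

#' Bias-corrected bootstrap percentile interval
#'
#' BC (not BCa: no acceleration term) percentile interval: with
#' \eqn{z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)}, the bounds
#' are the bootstrap quantiles at \eqn{\Phi(2z_0 \pm z_{\alpha/2})}. When
#' the bootstrap distribution is median-centred on the estimate
#' (\eqn{z_0 = 0}) this reduces to the plain percentile interval.
#'
#' @param boot_draws bootstrap replicate estimates.
#' @param estimate point estimate on the original data.
#' @param level confidence level.
#' @return \code{c(lower, upper)}.
#' @export
bc_interval <- function(boot_draws, estimate, level = 0.95) {
  B <- length(boot_draws)
  if (B < 2) stop("at least 2 bootstrap draws are required")
  prop <- mean(boot_draws < estimate)
  # degenerate bootstrap distributions: all draws equal the estimate
  if (prop == 0 && all(boot_draws == estimate))
    return(c(lower = estimate, upper = estimate))
  z0 <- stats::qnorm(min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  probs <- stats::pnorm(c(2 * z0 - z, 2 * z0 + z))
  q <- stats::quantile(boot_draws, probs, names = FALSE, type = 6)
  c(lower = q[1], upper = q[2])
}

#' Incremental cost-effectiveness by bootstrap regression
#'
#' Estimates the incremental QALY and incremental cost of individualised
#' vs annual screening by ordinary least squares (QALY on arm indicator,
#' optionally adjusted for baseline utility; cost on arm indicator), with
#' 95\% bias-corrected bootstrap confidence intervals from resampling
#' participants with replacement within arm.
#'
#' @param data participant-level data.frame: \code{arm}, \code{qaly},
#'   \code{cost}, and \code{baseline_utility} when adjusting.
#' @param adjust \code{"baseline-adjusted"} (default) or
#'   \code{"unadjusted"}.
#' @param iterations bootstrap replicates (default 1000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return List of class \code{cea_result}: \code{inc_qaly},
#'   \code{inc_cost}, each with \code{estimate}, \code{lower},
#'   \code{upper}; \code{draws} (data.frame of bootstrap (cost, qaly)
#'   pairs for the cost-effectiveness plane); \code{adjust},
#'   \code{iterations}, \code{redrawn} (degenerate resamples redrawn).
#' @export
incremental_cea <- function(data, adjust = c("baseline-adjusted", "unadjusted"),
                            iterations = 1000, level = 0.95, seed = NULL) {
  adjust <- match.arg(adjust)
  if (iterations < 2) stop("at least 2 bootstrap iterations are required")
  stopifnot(all(c("arm", "qaly", "cost") %in% names(data)))
  base <- if (adjust == "baseline-adjusted") data$baseline_utility else NULL
  if (adjust == "baseline-adjusted" && is.null(base))
    stop("`baseline_utility` column required for baseline adjustment")
  est_q <- .arm_effect(data$qaly, data$arm, base)
  est_c <- .arm_effect(data$cost, data$arm, NULL)

  by_arm <- split(seq_len(nrow(data)), data$arm)
  if (length(by_arm) < 2) stop("both arms must be present")
  redrawn <- 0L
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, iterations, 2)
    for (b in seq_len(iterations)) {
      repeat {
        ix <- unlist(lapply(by_arm, function(v) sample(v, length(v), replace = TRUE)),
                     use.names = FALSE)
        if (length(unique(data$arm[ix])) == 2) break
        redrawn <- redrawn + 1L
      }
      out[b, 1] <- .arm_effect(data$qaly[ix], data$arm[ix],
                               if (!is.null(base)) base[ix])
      out[b, 2] <- .arm_effect(data$cost[ix], data$arm[ix], NULL)
    }
    out
  })
  structure(list(
    inc_qaly = c(estimate = unname(est_q), bc_interval(draws[, 1], est_q, level)),
    inc_cost = c(estimate = unname(est_c), bc_interval(draws[, 2], est_c, level)),
    draws = data.frame(inc_qaly = draws[, 1], inc_cost = draws[, 2]),
    adjust = adjust, iterations = iterations, level = level,
    redrawn = redrawn
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  f <- function(v) sprintf("%.4f (%.4f, %.4f)", v["estimate"], v["lower"], v["upper"])
  cat("Within-trial cost-effectiveness (", x$adjust, ", ",
      x$iterations, " bootstrap iterations)\n", sep = "")
  cat("  incremental QALY:", f(x$inc_qaly), "\n")
  cat("  incremental cost:", f(x$inc_cost), "GBP\n")
  invisible(x)
}

#' Two-equation seemingly unrelated regression
#'
#' Feasible GLS for a cost equation and a QALY equation sharing the arm
#' regressor, with cross-equation error covariance estimated from the
#' per-equation OLS residuals. With identical regressor matrices or a
#' diagonal error covariance the estimator coincides with
#' equation-by-equation least squares.
#'
#' @param y1,X1 first-equation response and design matrix.
#' @param y2,X2 second-equation response and design matrix.
#' @return List with per-equation coefficient vectors \code{coef1},
#'   \code{coef2}, their covariance blocks \code{vcov1}, \code{vcov2}, and
#'   the estimated error covariance \code{sigma}.
#' @export
sur_fit <- function(y1, X1, y2, X2) {
  n <- length(y1)
  stopifnot(length(y2) == n, nrow(X1) == n, nrow(X2) == n)
  b1 <- stats::.lm.fit(X1, y1)$coefficients
  b2 <- stats::.lm.fit(X2, y2)$coefficients
  e1 <- y1 - X1 %*% b1; e2 <- y2 - X2 %*% b2
  S <- crossprod(cbind(e1, e2)) / n
  Sinv <- solve(S)
  k1 <- ncol(X1); k2 <- ncol(X2)
  A <- rbind(cbind(Sinv[1, 1] * crossprod(X1), Sinv[1, 2] * crossprod(X1, X2)),
             cbind(Sinv[2, 1] * crossprod(X2, X1), Sinv[2, 2] * crossprod(X2)))
  b <- c(Sinv[1, 1] * crossprod(X1, y1) + Sinv[1, 2] * crossprod(X1, y2),
         Sinv[2, 1] * crossprod(X2, y1) + Sinv[2, 2] * crossprod(X2, y2))
  V <- solve(A)
  beta <- drop(V %*% b)
  list(coef1 = beta[seq_len(k1)], coef2 = beta[k1 + seq_len(k2)],
       vcov1 = V[seq_len(k1), seq_len(k1), drop = FALSE],
       vcov2 = V[k1 + seq_len(k2), k1 + seq_len(k2), drop = FALSE],
       sigma = S)
}

#' Pooled cost-effectiveness across multiply imputed sets
#'
#' Fits the joint cost/QALY seemingly-unrelated-regression system on each
#' completed dataset and pools the two arm coefficients across imputations
#' by Rubin's rules.
#'
#' @param imputed list of completed data.frames, each with \code{arm},
#'   \code{qaly}, \code{cost} and (for adjustment) \code{baseline_utility}.
#' @param adjust as for \code{\link{incremental_cea}}.
#' @param level confidence level.
#' @return List of class \code{cea_result}-like: \code{inc_qaly},
#'   \code{inc_cost} (each the \code{\link{rubin_pool}} result), \code{m}.
#' @export
pooled_cea <- function(imputed, adjust = c("baseline-adjusted", "unadjusted"),
                       level = 0.95) {
  adjust <- match.arg(adjust)
  if (length(imputed) < 2) stop("at least 2 imputed sets are required")
  per_set <- lapply(imputed, function(d) {
    arm <- as.numeric(d$arm == "individualised")
    Xq <- if (adjust == "baseline-adjusted")
      cbind(1, arm, d$baseline_utility) else cbind(1, arm)
    Xc <- cbind(1, arm)
    s <- sur_fit(d$qaly, Xq, d$cost, Xc)
    c(q = unname(s$coef1[2]), q_var = s$vcov1[2, 2],
      c = unname(s$coef2[2]), c_var = s$vcov2[2, 2])
  })
  M <- do.call(rbind, per_set)
  list(inc_qaly = rubin_pool(M[, "q"], M[, "q_var"], level),
       inc_cost = rubin_pool(M[, "c"], M[, "c_var"], level),
       m = length(imputed), adjust = adjust)
}

#' Programme-level cost and appointment summary
#'
#' Arm totals of screening costs, per-participant means, percentage cost
#' reduction (individualised vs control, rounded to the integer the
#' programme reports) and percentage reduction in attended appointments
#' (1 decimal place).
#'
#' @param trial a \code{trial_dataset} (or a list with a \code{visits}
#'   data.frame carrying \code{id}, \code{attended} and a \code{participants}
#'   table carrying \code{id}, \code{arm}).
#' @param cs a \code{\link{cost_schedule}}.
#' @return List: \code{by_arm} (data.frame arm, participants, attended,
#'   missed, nhs_total, societal_total, nhs_mean), \code{nhs_reduction_pct},
#'   \code{societal_reduction_pct}, \code{appointment_reduction_pct}.
#' @export
programme_summary <- function(trial, cs = cost_schedule()) {
  v <- trial$visits
  p <- trial$participants
  arm_of <- stats::setNames(p$arm, p$id)
  v$arm <- arm_of[as.character(v$id)]
  by_arm <- do.call(rbind, lapply(c("control", "individualised"), function(a) {
    va <- v[v$arm == a, , drop = FALSE]
    att <- sum(va$attended); mis <- sum(!va$attended)
    costs <- participant_costs(att, mis, cs)
    data.frame(arm = a, participants = sum(p$arm == a),
               attended = att, missed = mis,
               nhs_total = costs[["nhs"]], societal_total = costs[["societal"]],
               nhs_mean = costs[["nhs"]] / sum(p$arm == a),
               stringsAsFactors = FALSE)
  }))
  ctrl <- by_arm[by_arm$arm == "control", ]
  ind <- by_arm[by_arm$arm == "individualised", ]
  if (ctrl$nhs_total == 0) stop("control-arm total cost is zero; reduction undefined")
  list(by_arm = by_arm,
       nhs_reduction_pct = round(100 * (ctrl$nhs_total - ind$nhs_total) / ctrl$nhs_total),
       societal_reduction_pct = round(100 * (ctrl$societal_total - ind$societal_total) /
                                        ctrl$societal_total),
       appointment_reduction_pct = round(100 * (ctrl$attended - ind$attended) /
                                           ctrl$attended, 1))
}

#' Synthetic utility series for the health-economics sample
#'
#' Generates already-valued utility indices (the tariff machinery that maps
#' questionnaire responses to indices is outside this package's scope):
#' baseline utility is drawn with most mass near full health
#' (1 - a gamma-distributed decrement, floored), and follow-up measurements
#' at each attended visit are the baseline plus small noise, preserving the
#' strong within-person correlation seen in practice. The EQ-VAS analogue
#' is generated on 0-100 and rescaled by division by 100.
#'
#' @param trial a \code{trial_dataset}.
#' @param instruments character vector of instrument labels.
#' @param noise_sd standard deviation of the follow-up perturbation.
#' @param seed integer seed.
#' @return data.frame \code{id}, \code{instrument}, \code{time_months},
#'   \code{utility}.
#' @export
generate_utility_series <- function(trial, instruments = c("eq5d", "eqvas", "hui3"),
                                    noise_sd = 0.05, seed = NULL) {
  p <- trial$participants
  v <- trial$visits
  with_seed(seed, {
    out <- lapply(instruments, function(ins) {
      u0 <- pmin(1 - stats::rgamma(nrow(p), shape = 1.2, scale = 0.12), 1)
      u0 <- pmax(u0, if (ins == "hui3") -0.36 else 0)
      rows <- lapply(seq_len(nrow(p)), function(i) {
        va <- v[v$id == p$id[i] & v$attended, , drop = FALSE]
        times <- c(0, va$actual_time)
        u <- c(u0[i], pmin(u0[i] + stats::rnorm(nrow(va), 0, noise_sd), 1))
        data.frame(id = p$id[i], instrument = ins, time_months = times,
                   utility = if (ins == "eqvas") round(pmax(u, 0) * 100) / 100 else u,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    do.call(rbind, out)
  })
}
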