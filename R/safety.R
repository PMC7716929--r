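#' Wilson score confidence interval for a proportion
#'
#' \deqn{\frac{p + z^2/2n}{1 + z^2/n} \;\pm\;
#'   \frac{z\sqrt{p(1-p)/n + z^2/4n^2}}{1 + z^2/n}}
#' with \eqn{z} the two-sided normal quantile for the confidence level.
#' Bounds always lie in \eqn{[0, 1]} and the interval contains \eqn{x/n}.
#'
#' @param x event count, \code{0 <= x <= n}.
#' @param n denominator, \code{n > 0}.
#' @param level confidence level (default 0.95, \eqn{z = 1.959964}).
#' @return Numeric vector \code{c(lower, upper)}.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  if (n <= 0) stop("`n` must be positive")
  if (x < 0 || x > n) stop("`x` must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(centre - half, 0), upper = min(centre + half, 1))
}

#' Newcombe score interval for a difference of proportions
#'
#' Square-and-add combination of the two arms' Wilson intervals for
#' \eqn{D = p_I - p_C} (individualised minus control): with Wilson bounds
#' \eqn{(l_1, u_1)} and \eqn{(l_2, u_2)},
#' \deqn{D - \sqrt{(p_I - l_1)^2 + (u_2 - p_C)^2} \;\le\; D \;\le\;
#'       D + \sqrt{(u_1 - p_I)^2 + (p_C - l_2)^2}.}
#' No continuity correction is applied. The interval always contains
#' \eqn{D} and is anti-symmetric under swapping the arms.
#'
#' @param x1,n1 individualised-arm events and denominator.
#' @param x2,n2 control-arm events and denominator.
#' @param level confidence level.
#' @return List: \code{D}, \code{lower}, \code{upper}, \code{p1}, \code{p2},
#'   \code{level}.
#' @export
newcombe_diff_ci <- function(x1, n1, x2, n2, level = 0.95) {
  w1 <- wilson_ci(x1, n1, level)
  w2 <- wilson_ci(x2, n2, level)
  p1 <- x1 / n1; p2 <- x2 / n2
  D <- p1 - p2
  list(D = D,
       lower = D - sqrt((p1 - w1[["lower"]])^2 + (w2[["upper"]] - p2)^2),
       upper = D + sqrt((w1[["upper"]] - p1)^2 + (p2 - w2[["lower"]])^2),
       p1 = p1, p2 = p2, level = level)
}

#' Equivalence verdict against a symmetric margin
#'
#' The arms are declared equivalent when the confidence interval for the
#' difference lies strictly inside \eqn{(-\delta, +\delta)}; an interval
#' touching the margin does not establish equivalence.
#'
#' @param ci numeric \code{c(lower, upper)} or the result of
#'   \code{\link{newcombe_diff_ci}}.
#' @param margin equivalence margin \eqn{\delta} (default 0.05).
#' @param strict use strict inequalities at the boundary (default TRUE).
#' @return \code{"equivalent"} or \code{"not-established"}.
#' @export
equivalence_verdict <- function(ci, margin = 0.05, strict = TRUE) {
  stopifnot(margin > 0)
  b <- if (is.list(ci)) c(ci$lower, ci$upper) else as.numeric(ci)
  inside <- if (strict) b[1] > -margin && b[2] < margin
            else b[1] >= -margin && b[2] <= margin
  if (inside) "equivalent" else "not-established"
}

#' Non-inferiority verdict against a one-sided margin
#'
#' The individualised arm is non-inferior when the lower confidence bound
#' for \eqn{D = p_I - p_C} exceeds \eqn{-\delta}.
#'
#' @param ci as for \code{\link{equivalence_verdict}}.
#' @param margin non-inferiority margin \eqn{\delta} (default 0.015).
#' @param strict strict inequality at the boundary (default TRUE).
#' @return \code{"non-inferior"} or \code{"not-established"}.
#' @export
noninferiority_verdict <- function(ci, margin = 0.015, strict = TRUE) {
  stopifnot(margin > 0)
  lo <- if (is.list(ci)) ci$lower else as.numeric(ci)[1]
  ok <- if (strict) lo > -margin else lo >= -margin
  if (ok) "non-inferior" else "not-established"
}

#' Risk-group subgroup analysis
#'
#' Per-risk-group Newcombe intervals for the arm difference (control
#' participants carry baseline risk-group labels computed by the risk
#' engine), plus a binomial generalised linear model (logit link) with arm,
#' risk group and their interaction as factors.
#'
#' @param data participant-level data.frame with \code{arm},
#'   \code{group0} and logical \code{outcome} columns (one of the analysis
#'   sets from \code{\link{build_analysis_sets}}).
#' @param level confidence level for the per-group intervals.
#' @return List: \code{by_group} (data.frame of per-group counts, D and CI
#'   bounds), \code{glm} (the fitted interaction model), \code{wald}
#'   (coefficient summary).
#' @export
subgroup_analysis <- function(data, level = 0.95) {
  groups <- intersect(c("high", "medium", "low"), unique(data$group0))
  rows <- lapply(groups, function(g) {
    d <- data[data$group0 == g, , drop = FALSE]
    n1 <- sum(d$arm == "individualised"); x1 <- sum(d$outcome[d$arm == "individualised"])
    n2 <- sum(d$arm == "control"); x2 <- sum(d$outcome[d$arm == "control"])
    if (n1 == 0 || n2 == 0) {
      warning("group ", g, " empty in one arm; skipped")
      return(NULL)
    }
    ci <- newcombe_diff_ci(x1, n1, x2, n2, level)
    data.frame(group = g, n1 = n1, x1 = x1, p1 = ci$p1,
               n2 = n2, x2 = x2, p2 = ci$p2,
               D = ci$D, lower = ci$lower, upper = ci$upper,
               stringsAsFactors = FALSE)
  })
  by_group <- do.call(rbind, rows)
  d <- data
  d$arm <- factor(d$arm, c("control", "individualised"))
  d$group0 <- factor(d$group0, groups)
  fit <- stats::glm(outcome ~ arm * group0, family = stats::binomial(), data = d)
  list(by_group = by_group, glm = fit,
       wald = summary(fit)$coefficients)
}

#' Multiply impute missing binary outcomes
#'
#' Proper multiple imputation from a binomial generalised linear model
#' (logit link) of the outcome on baseline characteristics, fitted to
#' complete cases: for each imputation the coefficient vector is drawn from
#' its approximate normal posterior and missing outcomes are drawn Bernoulli
#' at the implied probabilities.
#'
#' @param data data.frame with a logical/binary \code{outcome} column
#'   (NA = missing) and complete baseline predictor columns.
#' @param predictors character vector of baseline predictor columns.
#' @param m number of imputations (default 20).
#' @param seed integer seed.
#' @return List of \code{m} completed data.frames.
#' @export
impute_missing <- function(data, predictors, m = 20, seed = NULL) {
  miss <- is.na(data$outcome)
  if (!any(miss)) return(replicate(m, data, simplify = FALSE))
  fml <- stats::reformulate(predictors, response = "outcome")
  cc <- data[!miss, , drop = FALSE]
  cc$outcome <- as.integer(cc$outcome)
  fit <- stats::glm(fml, family = stats::binomial(), data = cc)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  L <- chol(V)
  X <- stats::model.matrix(stats::delete.response(stats::terms(fml)),
                           data[miss, , drop = FALSE])
  with_seed(seed, lapply(seq_len(m), function(k) {
    b <- beta + drop(t(L) %*% stats::rnorm(length(beta)))
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    out <- data
    out$outcome[miss] <- stats::runif(sum(miss)) < p
    out
  }))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; total
#' variance is \eqn{W + (1 + 1/m)B} with \eqn{W} the mean within-imputation
#' variance and \eqn{B} the between-imputation variance. The confidence
#' interval uses a t reference with the standard degrees of freedom
#' \eqn{(m-1)\{1 + W/((1+1/m)B)\}^2} (infinite when \eqn{B = 0}).
#'
#' @param estimates numeric vector of per-imputation estimates (length >= 2).
#' @param variances per-imputation squared standard errors.
#' @param level confidence level.
#' @return List: \code{estimate}, \code{variance}, \code{se}, \code{df},
#'   \code{lower}, \code{upper}, \code{within}, \code{between}, \code{m}.
#' @export
rubin_pool <- function(estimates, variances, level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling requires at least 2 imputations")
  stopifnot(length(variances) == m)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  tq <- stats::qt(1 - (1 - level) / 2, df)
  se <- sqrt(total)
  list(estimate = qbar, variance = total, se = se, df = df,
       lower = qbar - tq * se, upper = qbar + tq * se,
       within = W, between = B, m = m)
}

#' Deterministic simple-imputation fill rules
#'
#' Best/worst-case sensitivity fills for a missing binary outcome.
#'
#' @param data as for \code{\link{impute_missing}}.
#' @param rule \code{"all-attended"} (missing set TRUE) or
#'   \code{"none-attended"} (missing set FALSE).
#' @return Completed data.frame.
#' @export
simple_impute <- function(data, rule = c("all-attended", "none-attended")) {
  rule <- match.arg(rule)
  data$outcome[is.na(data$outcome)] <- (rule == "all-attended")
  data
}
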