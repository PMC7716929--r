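#' Cohort generating profile
#'
#' Bundles the distributional targets used by the synthetic cohort
#' generator: the baseline two-eye retinopathy state distribution, marginal
#' distributions for the clinical covariates, diabetes-type proportions,
#' attendance probabilities by arm and risk group, and the withdrawal
#' hazard. Defaults emulate a large English community screening population
#' (mostly type 2 diabetes, ~81\% with no retinopathy in either eye).
#'
#' Covariate families: right-skewed covariates (diabetes duration, HbA1c)
#' are log-normal; age, systolic blood pressure and total cholesterol are
#' normal truncated to plausible clinical ranges. Location/scale are
#' parameterised from the population median and interquartile range
#' (scale = IQR width / 1.349, on the log scale for log-normal families).
#'
#' @param state_probs probabilities of baseline states R0R0, R1R0, R1R1
#'   (normalised to sum to 1).
#' @param covariates named list of per-covariate parameter lists, each with
#'   \code{family} ("lognormal" or "truncnormal"), \code{median},
#'   \code{iqr} (length-2), and for truncated normal a \code{range}.
#' @param dm_type_probs proportions of type 1 / type 2 / unknown diabetes.
#' @param attendance matrix of attendance probabilities, rows
#'   \code{c("control", "individualised")}, columns
#'   \code{c("high", "medium", "low")}.
#' @param withdrawal_annual annual probability of withdrawal / loss to
#'   follow-up (converted internally to a constant hazard).
#' @param n_clinics number of screening clinics used as randomisation
#'   strata.
#' @return Object of class \code{cohort_profile}.
#' @export
cohort_profile <- function(
    state_probs = c(R0R0 = 0.812, R1R0 = 0.124, R1R1 = 0.063),
    covariates = list(
      age      = list(family = "truncnormal", median = 63.1, iqr = c(54.9, 70.7), range = c(14, 101)),
      duration = list(family = "lognormal",   median = 7.0,  iqr = c(4.2, 11.0), range = c(0.5, 66)),
      hba1c    = list(family = "lognormal",   median = 51,   iqr = c(44, 62), range = c(26, 155)),
      sbp      = list(family = "truncnormal", median = 130,  iqr = c(122, 138), range = c(84, 213)),
      chol     = list(family = "truncnormal", median = 4.0,  iqr = c(3.4, 4.7), range = c(1.4, 9.7))
    ),
    dm_type_probs = c(type1 = 0.040, type2 = 0.885, unknown = 0.075),
    attendance = rbind(
      control        = c(high = 0.773, medium = 0.817, low = 0.857),
      individualised = c(high = 0.723, medium = 0.822, low = 0.851)
    ),
    withdrawal_annual = 0.06,
    n_clinics = 8) {
  state_probs <- unlist(state_probs)
  if (anyNA(state_probs) || any(state_probs < 0) || any(state_probs > 1))
    stop("state probabilities must lie in [0, 1]")
  if (abs(sum(state_probs) - 1) > 0.01)
    stop("state probabilities must sum to 1 (within 1%)")
  state_probs <- state_probs / sum(state_probs)
  dm_type_probs <- unlist(dm_type_probs)
  if (any(dm_type_probs < 0)) stop("diabetes-type proportions must be non-negative")
  dm_type_probs <- dm_type_probs / sum(dm_type_probs)
  attendance <- as.matrix(attendance)
  if (any(attendance < 0 | attendance > 1))
    stop("attendance probabilities must lie in [0, 1]")
  if (withdrawal_annual < 0 || withdrawal_annual >= 1)
    stop("`withdrawal_annual` must lie in [0, 1)")
  structure(
    list(state_probs = state_probs, covariates = covariates,
         dm_type_probs = dm_type_probs, attendance = attendance,
         withdrawal_annual = withdrawal_annual,
         withdrawal_hazard = -log(1 - withdrawal_annual) / 12,
         n_clinics = as.integer(n_clinics)),
    class = "cohort_profile"
  )
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("Synthetic cohort profile\n")
  cat("  baseline states:",
      paste(sprintf("%s %.3f", names(x$state_probs), x$state_probs), collapse = ", "), "\n")
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  cat(sprintf("  withdrawal: %.1f%%/annum over %d clinics\n",
              100 * x$withdrawal_annual, x$n_clinics))
  invisible(x)
}

# location/scale from median + IQR; 1.349 = 2 * qnorm(0.75)
.cov_params <- function(spec) {
  width <- diff(spec$iqr)
  if (spec$family == "lognormal") {
    list(meanlog = log(spec$median),
         sdlog = (log(spec$iqr[2]) - log(spec$iqr[1])) / (2 * stats::qnorm(0.75)))
  } else {
    list(mean = spec$median, sd = width / (2 * stats::qnorm(0.75)),
         range = spec$range)
  }
}

.draw_covariate <- function(n, spec) {
  p <- .cov_params(spec)
  if (spec$family == "lognormal") {
    if (is.null(spec$range)) return(stats::rlnorm(n, p$meanlog, p$sdlog))
    lo <- stats::plnorm(spec$range[1], p$meanlog, p$sdlog)
    hi <- stats::plnorm(spec$range[2], p$meanlog, p$sdlog)
    stats::qlnorm(stats::runif(n, lo, hi), p$meanlog, p$sdlog)
  } else if (spec$family == "truncnormal") {
    # inverse-CDF truncated normal
    lo <- stats::pnorm(p$range[1], p$mean, p$sd)
    hi <- stats::pnorm(p$range[2], p$mean, p$sd)
    stats::qnorm(stats::runif(n, lo, hi), p$mean, p$sd)
  } else stop("unknown covariate family: ", spec$family)
}
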