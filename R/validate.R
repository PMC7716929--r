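#' Area under the ROC curve by rank comparison
#'
#' Mann-Whitney form of the AUC: the probability that a randomly chosen
#' case has a higher predicted risk than a randomly chosen non-case, ties
#' counted one half (midranks).
#'
#' @param risk numeric vector of predicted risks.
#' @param outcome logical/0-1 vector of observed outcomes.
#' @return AUC in \eqn{[0, 1]}, or \code{NA} when all outcomes are
#'   identical (discrimination undefined).
#' @export
auc_rank <- function(risk, outcome) {
  outcome <- as.logical(outcome)
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(risk)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a risk threshold
#'
#' Classifies predicted risk >= \code{tau} as test-positive and tabulates
#' against the observed outcome.
#'
#' @inheritParams auc_rank
#' @param tau risk threshold (default 0.025).
#' @return Named vector \code{c(sensitivity, specificity)}.
#' @export
sens_spec_at <- function(risk, outcome, tau = 0.025) {
  outcome <- as.logical(outcome)
  pos <- risk >= tau
  c(sensitivity = sum(pos & outcome) / sum(outcome),
    specificity = sum(!pos & !outcome) / sum(!outcome))
}

#' Concordance index for time-to-screen-positive
#'
#' The probability that, of a usable pair of participants, the one with the
#' higher predicted risk reaches the screen-positive state first. A pair is
#' usable when the shorter of the two times ends in an event; ties in
#' predicted risk count one half. Event times tied with each other are not
#' usable.
#'
#' @param risk predicted risks.
#' @param time time to screen-positive or censoring (months).
#' @param status 1 if screen-positive at \code{time}, 0 if censored.
#' @return List with \code{cindex}, \code{concordant}, \code{tied},
#'   \code{usable}.
#' @export
concordance_index <- function(risk, time, status) {
  n <- length(risk)
  conc <- ties <- usable <- 0
  idx <- seq_len(n)
  for (i in which(status == 1)) {
    j <- idx[time[i] < time | (time[i] == time & status == 0 & idx != i)]
    usable <- usable + length(j)
    conc <- conc + sum(risk[i] > risk[j])
    ties <- ties + sum(risk[i] == risk[j])
  }
  list(cindex = if (usable > 0) (conc + ties / 2) / usable else NA_real_,
       concordant = conc, tied = ties, usable = usable)
}

#' @keywords internal
#' Per-participant baseline summary from panel data: baseline state and
#' covariates, first screen-positive time (Inf if none) and last
#' observation time.
.panel_baseline <- function(data, covariates, absorbing = "SP") {
  ord <- order(data$id, data$time)
  data <- data[ord, , drop = FALSE]
  by_id <- split(seq_len(nrow(data)), data$id)
  rows <- lapply(by_id, function(ix) {
    first <- ix[1L]
    sp <- ix[data$state[ix] == absorbing]
    out <- data[first, c("id", "state", covariates), drop = FALSE]
    out$sp_time <- if (length(sp)) min(data$time[sp]) else Inf
    out$last_time <- max(data$time[ix])
    out
  })
  res <- do.call(rbind, rows)
  names(res)[names(res) == "state"] <- "state0"
  rownames(res) <- NULL
  res
}

#' Validate a fitted risk model against panel outcomes
#'
#' Computes the discrimination metrics of the risk-calculation engine on a
#' panel dataset: per-horizon AUC, sensitivity and specificity at the risk
#' threshold, and the concordance index for time to screen-positive, with
#' optional optimism correction by the bootstrap (refit on each resample,
#' evaluate on the original data, subtract the average optimism).
#'
#' The outcome for horizon \eqn{h} is ascertainment of the screen-positive
#' state at or before \eqn{h} months; participants neither screen-positive
#' nor followed to \eqn{h} are excluded from that horizon (their outcome is
#' not ascertainable).
#'
#' @param fit an \code{msm_fit} from \code{\link{fit_multistate_model}}.
#' @param data the panel data the metrics are evaluated on.
#' @param horizons risk horizons in months.
#' @param tau risk threshold for sensitivity/specificity.
#' @param boot number of optimism-correction bootstrap replicates (0 skips
#'   correction; the programme convention is at least 100).
#' @param seed seed for the bootstrap.
#' @return List of class \code{validation_report}: \code{metrics}
#'   (data.frame horizon x {auc, sensitivity, specificity}),
#'   \code{cindex}, optimism-corrected columns when \code{boot > 0}, and
#'   \code{boot}.
#' @export
validate_model <- function(fit, data, horizons = c(6, 12, 24), tau = 0.025,
                           boot = 0, seed = NULL) {
  stopifnot(inherits(fit, "msm_fit"))
  covs <- fit$covariates
  base <- .panel_baseline(data, covs, fit$model$absorbing)
  base <- base[base$state0 != fit$model$absorbing, , drop = FALSE]

  eval_metrics <- function(model, newbase) {
    sapply(horizons, function(h) {
      ok <- newbase$sp_time <= h | newbase$last_time >= h
      b <- newbase[ok, , drop = FALSE]
      risk <- vapply(seq_len(nrow(b)), function(i)
        screen_positive_risk(model, b$state0[i],
                             if (length(covs)) as.list(b[i, covs, drop = FALSE]) else NULL,
                             h), numeric(1))
      outcome <- b$sp_time <= h
      c(auc = auc_rank(risk, outcome), sens_spec_at(risk, outcome, tau))
    })
  }
  apparent <- eval_metrics(fit$model, base)
  metrics <- data.frame(horizon = horizons, auc = apparent["auc", ],
                        sensitivity = apparent["sensitivity", ],
                        specificity = apparent["specificity", ])

  hmax <- max(horizons)
  risk_max <- vapply(seq_len(nrow(base)), function(i)
    screen_positive_risk(fit$model, base$state0[i],
                         if (length(covs)) as.list(base[i, covs, drop = FALSE]) else NULL,
                         hmax), numeric(1))
  ctime <- pmin(base$sp_time, base$last_time)
  cstat <- as.integer(is.finite(base$sp_time) & base$sp_time <= base$last_time)
  cind <- concordance_index(risk_max, ctime, cstat)$cindex

  rep <- list(metrics = metrics, cindex = cind, tau = tau, boot = boot)
  if (boot > 0) {
    ids <- unique(data$id)
    optim_sum <- matrix(0, nrow(apparent), length(horizons))
    with_seed(seed, for (b in seq_len(boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      bd <- do.call(rbind, lapply(seq_along(take), function(k) {
        d <- data[data$id == take[k], , drop = FALSE]; d$id <- k; d
      }))
      bfit <- suppressWarnings(
        fit_multistate_model(bd, fit$transitions, covariates = covs,
                             hessian = FALSE))
      boot_app <- eval_metrics(bfit$model, .panel_baseline(bd, covs, fit$model$absorbing))
      orig <- eval_metrics(bfit$model, base)
      optim_sum <- optim_sum + (boot_app - orig)
    })
    optimism <- optim_sum / boot
    metrics$auc_corrected <- metrics$auc - optimism["auc", ]
    metrics$sensitivity_corrected <- metrics$sensitivity - optimism["sensitivity", ]
    metrics$specificity_corrected <- metrics$specificity - optimism["specificity", ]
    rep$metrics <- metrics
  }
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Risk-engine validation\n")
  print(round(as.data.frame(x$metrics), 3))
  cat(sprintf("  C-index (at %d-month risk): %.3f\n",
              max(x$metrics$horizon), x$cindex))
  invisible(x)
}
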