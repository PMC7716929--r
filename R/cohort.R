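#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic baseline cohort
#'
#' Draws \code{n} participants with baseline covariates, diabetes type,
#' clinic (randomisation stratum) and two-eye retinopathy state from a
#' \code{\link{cohort_profile}}. Covariates are sampled independently given
#' the profile's marginal families; dependence between covariates and
#' progression risk is induced downstream by the covariate effects of the
#' generating multi-state model, not hard-coded here. The
#' \code{prior_ret} indicator records retinopathy at the previous screen and
#' is set from the baseline state.
#'
#' @param n number of participants (0 gives an empty cohort).
#' @param profile a \code{\link{cohort_profile}}.
#' @param seed integer seed; the draw is deterministic given the seed and
#'   leaves the caller's RNG state untouched. \code{NULL} uses the current
#'   RNG stream.
#' @return A data.frame with one row per participant: \code{id},
#'   \code{clinic}, \code{age} (years), \code{duration} (years),
#'   \code{hba1c} (mmol/mol), \code{sbp} (mmHg), \code{chol} (mmol/l),
#'   \code{dm_type}, \code{prior_ret} (0/1), \code{state0}.
#' @export
generate_baseline_cohort <- function(n, profile = cohort_profile(), seed = NULL) {
  stopifnot(inherits(profile, "cohort_profile"), n >= 0)
  n <- as.integer(n)
  empty <- data.frame(id = integer(), clinic = integer(), age = numeric(),
                      duration = numeric(), hba1c = numeric(), sbp = numeric(),
                      chol = numeric(), dm_type = character(),
                      prior_ret = integer(), state0 = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  with_seed(seed, {
    covs <- lapply(profile$covariates, function(sp) .draw_covariate(n, sp))
    state0 <- sample(names(profile$state_probs), n, replace = TRUE,
                     prob = profile$state_probs)
    data.frame(
      id = seq_len(n),
      clinic = sample.int(profile$n_clinics, n, replace = TRUE),
      age = covs$age, duration = covs$duration, hba1c = covs$hba1c,
      sbp = covs$sbp, chol = covs$chol,
      dm_type = sample(names(profile$dm_type_probs), n, replace = TRUE,
                       prob = profile$dm_type_probs),
      prior_ret = as.integer(state0 != "R0R0"),
      state0 = state0,
      stringsAsFactors = FALSE
    )
  })
}

#' Default disease-progression model
#'
#' A plausibly calibrated generating ("truth") model for the synthetic
#' cohort: allowed transitions R0R0 <-> R1R0 <-> R1R1 (background
#' retinopathy may regress between screens) and a screen-positive exit from
#' every observable state, including directly from R0R0 (maculopathy can
#' arise without prior background retinopathy). Baseline intensities are per
#' month; covariate effects are log-linear on the progression and
#' screen-positive intensities, centred near the cohort means, so that
#' longer diabetes duration and higher HbA1c shift participants towards the
#' shorter-interval risk groups.
#'
#' @param beta_scale multiplier on the covariate effects (0 gives a
#'   covariate-free model).
#' @return An \code{msm_model}.
#' @export
default_progression_model <- function(beta_scale = 1) {
  tr <- rbind(c("R0R0", "R1R0"), c("R1R0", "R0R0"),
              c("R1R0", "R1R1"), c("R1R1", "R1R0"),
              c("R0R0", "SP"), c("R1R0", "SP"), c("R1R1", "SP"))
  log_q0 <- log(c(0.008, 0.020, 0.010, 0.005, 0.0003, 0.0012, 0.004))
  covs <- c("duration", "hba1c", "sbp", "chol", "prior_ret")
  beta <- matrix(0, nrow(tr), length(covs), dimnames = list(NULL, covs))
  progress <- c(1, 3, 5, 6, 7)  # rows: onset, worsening and SP exits
  beta[progress, "duration"]  <- 0.030
  beta[progress, "hba1c"]     <- 0.015
  beta[progress, "sbp"]       <- 0.005
  beta[progress, "chol"]      <- 0.080
  beta[progress, "prior_ret"] <- 0.300
  beta <- beta * beta_scale
  centers <- c(duration = 8.0, hba1c = 54, sbp = 130, chol = 4.1,
               prior_ret = 0.2)
  multistate_model(tr, log_q0, beta, centers)
}

#' Simulate a true disease trajectory
#'
#' Continuous-time Markov simulation of a participant's true state path:
#' exponential holding times with the total exit rate of the current state,
#' destination drawn with probability proportional to the transition
#' intensities. The screen-positive state is absorbing. Covariates are
#' frozen at their supplied values for the whole path.
#'
#' @param state0 starting state.
#' @param model generating \code{msm_model}.
#' @param z named covariate values for the participant.
#' @param horizon path length in months (> 0).
#' @param seed optional integer seed.
#' @return List of class \code{state_path} with \code{times} (jump times,
#'   starting at 0) and \code{states}; the path is right-continuous and
#'   piecewise constant.
#' @export
sample_progression_path <- function(state0, model, z = NULL, horizon = 27,
                                    seed = NULL) {
  stopifnot(horizon > 0, state0 %in% model$states)
  Q <- intensity_matrix(model, z)
  if (any(Q[upper.tri(Q) | lower.tri(Q)] < 0)) stop("negative intensity in model")
  with_seed(seed, {
    times <- 0; states <- state0; t <- 0; s <- state0
    repeat {
      rate <- -Q[s, s]
      if (s == model$absorbing || rate <= 0) break
      t <- t + stats::rexp(1, rate)
      if (t >= horizon) break
      dest <- Q[s, ]; dest[s] <- 0
      s <- sample(model$states, 1, prob = dest)
      times <- c(times, t); states <- c(states, s)
    }
    structure(list(times = times, states = states, horizon = horizon),
              class = "state_path")
  })
}

#' State occupied by a path at given times
#'
#' @param path a \code{state_path}.
#' @param t numeric vector of times in months.
#' @return Character vector of states (right-continuous evaluation).
#' @export
path_state_at <- function(path, t) {
  idx <- findInterval(t, path$times)
  path$states[pmax(idx, 1L)]
}

#' Simulate attendance at a screening invitation
#'
#' Bernoulli attendance with the arm- and risk-group-specific probability
#' from the profile; attenders receive an actual visit time uniform within
#' the 90-day (3-month) attendance window after the invitation.
#'
#' @param invitation_time invitation time in months (>= 0).
#' @param arm \code{"control"} or \code{"individualised"}.
#' @param group risk group \code{"high"}, \code{"medium"} or \code{"low"}.
#' @param profile a \code{\link{cohort_profile}}; its \code{attendance}
#'   matrix supplies the probability.
#' @param prob optional probability overriding the profile lookup.
#' @param window attendance window in months (default 3, i.e. 90 days).
#' @param seed optional integer seed.
#' @return List with \code{attended} (logical) and \code{actual_time}
#'   (months, \code{NA} if not attended).
#' @export
sample_attendance <- function(invitation_time, arm = "control", group = "low",
                              profile = cohort_profile(), prob = NULL,
                              window = 3, seed = NULL) {
  stopifnot(invitation_time >= 0)
  if (is.null(prob)) prob <- profile$attendance[arm, group]
  with_seed(seed, {
    attended <- stats::runif(1) < prob
    list(attended = attended,
         actual_time = if (attended)
           stats::runif(1, invitation_time, invitation_time + window) else NA_real_)
  })
}

#' Simulate a screening panel dataset
#'
#' Emulates a risk-engine development dataset: draws a baseline cohort,
#' simulates each participant's true trajectory under the generating model,
#' and records the state observed at a fixed grid of screening visits.
#' Observation stops at the first visit where the participant is seen
#' screen-positive (the absorbing state is recorded once).
#'
#' @param n number of participants.
#' @param model generating \code{msm_model}.
#' @param visit_times observation times in months (must start at 0).
#' @param profile \code{\link{cohort_profile}} for covariate generation;
#'   covariate columns required by the model are carried into the panel.
#' @param cohort optional pre-generated cohort (overrides \code{n} and
#'   \code{profile}).
#' @param seed integer seed.
#' @return Panel data.frame: \code{id}, \code{time}, \code{state} plus the
#'   model's covariate columns, suitable for
#'   \code{\link{fit_multistate_model}}.
#' @export
simulate_panel <- function(n = NULL, model, visit_times = seq(0, 60, by = 12),
                           profile = cohort_profile(), cohort = NULL,
                           seed = NULL) {
  stopifnot(visit_times[1] == 0, !is.unsorted(visit_times, strictly = TRUE))
  with_seed(seed, {
    if (is.null(cohort)) cohort <- generate_baseline_cohort(n, profile)
    covs <- colnames(model$beta)
    horizon <- max(visit_times) + 1
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      z <- if (length(covs)) as.list(cohort[i, covs]) else NULL
      path <- sample_progression_path(cohort$state0[i], model, z, horizon)
      s <- path_state_at(path, visit_times)
      sp <- which(s == model$absorbing)
      keep <- if (length(sp)) seq_len(sp[1L]) else seq_along(visit_times)
      out <- data.frame(id = cohort$id[i], time = visit_times[keep],
                        state = s[keep], stringsAsFactors = FALSE)
      for (v in covs) out[[v]] <- cohort[[v]][i]
      out
    })
    do.call(rbind, rows)
  })
}
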