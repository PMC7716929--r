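#' Stratified permuted-block randomisation
#'
#' Allocates participants 1:1 to the control (annual) and individualised
#' arms within strata defined by clinic and age band, using permuted blocks
#' of random size 4 or 6 for adults (age >= 16) and blocks of 2 for
#' children, so that within every completed block the arms are exactly
#' balanced.
#'
#' @param cohort baseline cohort data.frame with \code{id}, \code{clinic}
#'   and \code{age} columns.
#' @param block_sizes_adult,block_sizes_child candidate block sizes drawn
#'   uniformly per block.
#' @param age_cut age in years separating the two banding schemes.
#' @param seed integer seed; allocation is deterministic given the seed.
#' @return data.frame \code{id}, \code{stratum}, \code{arm}
#'   (\code{"control"} / \code{"individualised"}), in cohort order.
#' @export
randomise <- function(cohort, block_sizes_adult = c(4, 6),
                      block_sizes_child = 2, age_cut = 16, seed = NULL) {
  if (anyNA(cohort$clinic) || anyNA(cohort$age)) stop("unknown stratum")
  band <- ifelse(cohort$age >= age_cut, "adult", "child")
  stratum <- paste(cohort$clinic, band, sep = "/")
  arm <- character(nrow(cohort))
  with_seed(seed, {
    for (s in unique(stratum)) {
      ix <- which(stratum == s)
      sizes <- if (grepl("/adult$", s)) block_sizes_adult else block_sizes_child
      seq_arm <- character(0)
      while (length(seq_arm) < length(ix)) {
        b <- if (length(sizes) > 1) sample(sizes, 1) else sizes
        seq_arm <- c(seq_arm, sample(rep(c("control", "individualised"), b / 2)))
      }
      arm[ix] <- seq_arm[seq_along(ix)]
    }
  })
  data.frame(id = cohort$id, stratum = stratum, arm = arm,
             stringsAsFactors = FALSE)
}

#' @keywords internal
#' 6/12/24-month screen-positive risks from one matrix exponential:
#' P(12) = P(6)^2, P(24) = P(12)^2.
.risk_triple <- function(model, state, z) {
  Q <- intensity_matrix(model, z)
  P6 <- as.matrix(Matrix::expm(Q * 6))
  P12 <- P6 %*% P6
  P24 <- P12 %*% P12
  i <- match(state, model$states); j <- match(model$absorbing, model$states)
  pmin(pmax(c(risk6 = P6[i, j], risk12 = P12[i, j], risk24 = P24[i, j]), 0), 1)
}

#' Trial simulation configuration
#'
#' @param followup follow-up in months over which invitations are issued.
#' @param window attendance window after an invitation (months; 90 days).
#' @param econ_lag additional scheduling lag allowed at the end of
#'   follow-up for the economic horizon (months; a further 90 days).
#' @param tau risk threshold for interval allocation.
#' @param stdr_fraction fraction of screen-positive results confirmed as
#'   sight-threatening diabetic retinopathy on clinical examination; the
#'   remainder are false positives / other eye disease and re-enter recall.
#' @param deviation_rate probability that an individualised participant is
#'   assigned a wrong interval at baseline (protocol deviation injection
#'   for per-protocol vs intention-to-treat testing).
#' @param baseline_group_probs optional probabilities \code{c(high, medium,
#'   low)}; when supplied, baseline risk groups are drawn from this mix
#'   (calibration mode) instead of computed by the risk engine, which is
#'   still used for reassignment at follow-up visits.
#' @return List of class \code{trial_config}.
#' @export
trial_config <- function(followup = 24, window = 3, econ_lag = 3,
                         tau = 0.025, stdr_fraction = 0.24,
                         deviation_rate = 0, baseline_group_probs = NULL) {
  if (!is.null(baseline_group_probs)) {
    baseline_group_probs <- unlist(baseline_group_probs)
    stopifnot(length(baseline_group_probs) == 3,
              abs(sum(baseline_group_probs) - 1) < 0.01)
    names(baseline_group_probs) <- c("high", "medium", "low")
  }
  structure(list(followup = followup, window = window, econ_lag = econ_lag,
                 tau = tau, stdr_fraction = stdr_fraction,
                 deviation_rate = deviation_rate,
                 baseline_group_probs = baseline_group_probs),
            class = "trial_config")
}

.interval_of <- c(high = 6, medium = 12, low = 24)
.group_of <- function(interval) names(.interval_of)[match(interval, .interval_of)]

#' Simulate the two-arm screening trial
#'
#' Runs the randomised trial over the synthetic cohort: control participants
#' are invited at 12-month multiples; individualised participants at the
#' risk-engine-allocated interval, reassessed from the observed state and
#' covariates at every attended visit. Attendance is drawn with the arm- and
#' baseline-risk-group-specific probability; attended visits observe the
#' true state at the (uniformly jittered) actual visit time. A
#' screen-positive observation is confirmed as sight-threatening diabetic
#' retinopathy with probability \code{stdr_fraction}, after which the
#' participant exits routine recall; false positives re-enter the trial
#' (their trajectory restarts from the pre-screen-positive state).
#' Withdrawal/loss to follow-up is a constant hazard cancelling all later
#' invitations.
#'
#' @param cohort baseline cohort from \code{\link{generate_baseline_cohort}}.
#' @param assignments arm assignments from \code{\link{randomise}}.
#' @param rce risk-calculation engine (\code{msm_model}) used for interval
#'   allocation.
#' @param truth generating \code{msm_model} for the true disease paths
#'   (defaults to \code{rce}).
#' @param profile \code{\link{cohort_profile}} supplying attendance and
#'   withdrawal behaviour.
#' @param config a \code{\link{trial_config}}.
#' @param seed integer seed.
#' @return List of class \code{trial_dataset}: \code{participants}
#'   (arm, baseline group, deviation/withdrawal/analysis-set flags,
#'   first-follow-up attendance, STDR outcome) and \code{visits} (one row
#'   per invitation).
#' @export
run_trial <- function(cohort, assignments, rce, truth = rce,
                      profile = cohort_profile(), config = trial_config(),
                      seed = NULL) {
  stopifnot(nrow(cohort) == nrow(assignments))
  covs <- colnames(rce$beta)
  tcovs <- colnames(truth$beta)
  horizon <- config$followup + config$window + config$econ_lag
  n <- nrow(cohort)
  ids <- cohort$id
  state0s <- cohort$state0
  cov_cols <- lapply(cohort, identity)
  zvec <- function(which_covs, i) {
    if (!length(which_covs)) return(NULL)
    stats::setNames(lapply(which_covs, function(v) cov_cols[[v]][i]), which_covs)
  }
  with_seed(seed, {
    # participant-level accumulators
    p_group0 <- character(n); p_dev <- logical(n); p_wd <- rep(NA_real_, n)
    p_first_att <- rep(NA, n); p_first_inv <- rep(NA_real_, n)
    p_stdr <- logical(n); p_stdr_time <- rep(NA_real_, n)
    # visit-level accumulators: one short vector per participant, bound once
    vl_id <- vl_inv <- vl_att <- vl_act <- vl_state <- vl_sp <- vl_stdr <-
      vl_next <- vector("list", n)
    for (i in seq_len(n)) {
      arm <- assignments$arm[i]
      zr <- zvec(covs, i)
      zt <- zvec(tcovs, i)
      path <- sample_progression_path(state0s[i], truth, zt, horizon)
      wd <- if (profile$withdrawal_hazard > 0)
        stats::rexp(1, profile$withdrawal_hazard) else Inf

      if (!is.null(config$baseline_group_probs)) {
        group0 <- sample(names(config$baseline_group_probs), 1,
                         prob = config$baseline_group_probs)
      } else {
        group0 <- allocate_interval(.risk_triple(rce, state0s[i], zr),
                                    config$tau)$group
      }
      deviated <- FALSE
      interval <- .interval_of[[group0]]
      if (arm == "individualised" && config$deviation_rate > 0 &&
          stats::runif(1) < config$deviation_rate) {
        deviated <- TRUE
        interval <- sample(setdiff(unname(.interval_of), interval), 1)
      }
      p_attend <- profile$attendance[arm, group0]

      invite <- if (arm == "control") 12 else interval
      first <- TRUE
      stdr_time <- NA_real_
      w_inv <- w_act <- w_next <- numeric(0)
      w_att <- w_sp <- w_stdr <- logical(0); w_state <- character(0)
      while (invite <= config$followup + 1e-9 && invite < wd) {
        att <- stats::runif(1) < p_attend
        actual <- NA_real_; s_obs <- NA_character_
        sp <- FALSE; stdr <- FALSE
        if (att) {
          actual <- stats::runif(1, invite, invite + config$window)
          s <- path_state_at(path, actual)
          s_obs <- s
          if (s == truth$absorbing) {
            sp <- TRUE
            if (stats::runif(1) < config$stdr_fraction) {
              stdr <- TRUE
              stdr_time <- actual
            } else {
              # false positive: re-enter from the pre-absorption state
              k <- length(path$states)
              prev <- if (k >= 2) path$states[k - 1L] else state0s[i]
              cont <- sample_progression_path(prev, truth, zt,
                                              max(horizon - actual, 0.001))
              # restart at `actual`; earlier times are never queried again
              path <- structure(list(times = c(0, cont$times[-1] + actual),
                                     states = cont$states, horizon = horizon),
                                class = "state_path")
              s <- prev
            }
          }
          if (!stdr && arm == "individualised") {
            interval <- allocate_interval(.risk_triple(rce, s, zr),
                                          config$tau)$interval
          }
        }
        nxt <- if (arm == "control") 12 else interval
        w_inv <- c(w_inv, invite); w_att <- c(w_att, att)
        w_act <- c(w_act, actual); w_state <- c(w_state, s_obs)
        w_sp <- c(w_sp, sp); w_stdr <- c(w_stdr, stdr); w_next <- c(w_next, nxt)
        if (first) {
          p_first_att[i] <- att; p_first_inv[i] <- invite; first <- FALSE
        }
        if (stdr) break  # confirmed STDR exits routine recall
        invite <- if (arm == "control") 12 * (floor(invite / 12) + 1)
                  else invite + interval
      }
      if (length(w_inv)) {
        vl_id[[i]] <- rep(ids[i], length(w_inv))
        vl_inv[[i]] <- w_inv; vl_att[[i]] <- w_att; vl_act[[i]] <- w_act
        vl_state[[i]] <- w_state; vl_sp[[i]] <- w_sp; vl_stdr[[i]] <- w_stdr
        vl_next[[i]] <- w_next
      }
      p_group0[i] <- group0; p_dev[i] <- deviated
      p_wd[i] <- if (is.finite(wd)) wd else NA_real_
      p_stdr[i] <- !is.na(stdr_time) &&
        stdr_time <= config$followup + config$window
      p_stdr_time[i] <- stdr_time
    }
    participants <- data.frame(
      id = ids, arm = assignments$arm, stratum = assignments$stratum,
      group0 = p_group0, deviated = p_dev, withdrawal_time = p_wd,
      first_followup_attended = p_first_att, first_invitation = p_first_inv,
      stdr = p_stdr, stdr_time = p_stdr_time, stringsAsFactors = FALSE)
    participants <- cbind(participants,
                          cohort[, setdiff(names(cohort), "id"), drop = FALSE])
    rownames(participants) <- NULL
    visits <- data.frame(
      id = unlist(vl_id), invitation = unlist(vl_inv),
      attended = unlist(vl_att), actual_time = unlist(vl_act),
      state_obs = unlist(vl_state), screen_positive = unlist(vl_sp),
      stdr_confirmed = unlist(vl_stdr), next_interval = unlist(vl_next),
      stringsAsFactors = FALSE)
    structure(list(participants = participants, visits = visits,
                   config = config),
              class = "trial_dataset")
  })
}

#' @export
print.trial_dataset <- function(x, ...) {
  p <- x$participants
  cat(sprintf("Trial dataset: %d participants (%d control / %d individualised), %d invitations\n",
              nrow(p), sum(p$arm == "control"), sum(p$arm == "individualised"),
              nrow(x$visits)))
  cat(sprintf("  baseline groups (individualised): %s\n",
              paste(utils::capture.output(table(p$group0[p$arm == "individualised"])),
                    collapse = " ")))
  invisible(x)
}

#' Build per-protocol and intention-to-treat analysis sets
#'
#' Derives the analysis datasets for (a) attendance at the first follow-up
#' visit and (b) sight-threatening diabetic retinopathy within follow-up
#' (+ window). The per-protocol set excludes interval-assignment protocol
#' deviations and participants withdrawn before their first invitation; the
#' intention-to-treat set keeps every randomised participant, with
#' unobserved outcomes counted as non-events (configurable upstream via
#' imputation).
#'
#' @param trial a \code{trial_dataset} from \code{\link{run_trial}}.
#' @return List with, per outcome (\code{attendance}, \code{stdr}) and per
#'   approach (\code{pp}, \code{itt}): a participant-level data.frame
#'   (\code{id}, \code{arm}, \code{group0}, \code{outcome}) and a count
#'   table by arm and by arm x group with events \code{x} and denominators
#'   \code{n}.
#' @export
build_analysis_sets <- function(trial) {
  p <- trial$participants
  wd_before_first <- !is.na(p$withdrawal_time) & !is.na(p$first_invitation) &
    p$withdrawal_time < p$first_invitation
  never_invited <- is.na(p$first_invitation)  # withdrawn before any invitation
  pp_keep <- !p$deviated & !wd_before_first & !never_invited

  make <- function(keep, outcome) {
    d <- data.frame(id = p$id[keep], arm = p$arm[keep], group0 = p$group0[keep],
                    outcome = outcome[keep], stringsAsFactors = FALSE)
    d$outcome[is.na(d$outcome)] <- FALSE
    counts <- do.call(rbind, lapply(c("overall", "high", "medium", "low"),
      function(g) {
        dd <- if (g == "overall") d else d[d$group0 == g, , drop = FALSE]
        do.call(rbind, lapply(c("control", "individualised"), function(a) {
          da <- dd[dd$arm == a, , drop = FALSE]
          data.frame(group = g, arm = a, n = nrow(da), x = sum(da$outcome),
                     stringsAsFactors = FALSE)
        }))
      }))
    list(data = d, counts = counts)
  }
  list(
    attendance = list(pp = make(pp_keep, p$first_followup_attended),
                      itt = make(rep(TRUE, nrow(p)), p$first_followup_attended)),
    stdr = list(pp = make(!p$deviated & !never_invited, p$stdr),
                itt = make(rep(TRUE, nrow(p)), p$stdr))
  )
}

#' Two-by-two table as a proportion difference
#'
#' @param counts count table from \code{\link{build_analysis_sets}} (rows
#'   for one subgroup, both arms).
#' @return List \code{x1, n1} (individualised), \code{x2, n2} (control).
#' @export
counts_to_diff <- function(counts) {
  ci <- counts[counts$arm == "individualised", ]
  cc <- counts[counts$arm == "control", ]
  list(x1 = ci$x, n1 = ci$n, x2 = cc$x, n2 = cc$n)
}
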