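#' Retinopathy state space
#'
#' The model operates on two-eye retinopathy states: \code{R0R0} (no
#' retinopathy in either eye), \code{R1R0} (background retinopathy in one
#' eye), \code{R1R1} (background retinopathy in both eyes) and \code{SP}
#' (screen-positive: referable retinopathy/maculopathy, ungradable images or
#' other significant eye disease). \code{SP} is absorbing.
#'
#' @return Character vector of state labels in canonical order.
#' @export
retinopathy_states <- function() c("R0R0", "R1R0", "R1R1", "SP")

#' Construct a covariate-dependent continuous-time multi-state model
#'
#' Defines a continuous-time Markov model on the retinopathy state space in
#' which each allowed transition \eqn{r \to s} has intensity
#' \deqn{q_{rs}(z) = \exp\{\log q^0_{rs} + \beta_{rs} \cdot (z - \bar z)\},}
#' a log-linear (proportional-intensity) function of the covariate vector
#' \eqn{z}. Covariates are centred at stored constants \eqn{\bar z} so that
#' the baseline intensities are interpretable at the centring point.
#'
#' @param transitions two-column character matrix (or data.frame) of allowed
#'   transitions, one row per ordered pair \code{from -> to}. The absorbing
#'   state must have no outgoing transitions.
#' @param log_q0 numeric vector of baseline log-intensities, one per row of
#'   \code{transitions} (per month).
#' @param beta numeric matrix of covariate effects, rows matching
#'   \code{transitions}, columns named by covariate. May have zero columns
#'   for a covariate-free model.
#' @param centers named numeric vector of centring constants, one per
#'   column of \code{beta}.
#' @param states character vector of state labels; defaults to
#'   \code{\link{retinopathy_states}}.
#' @param absorbing label of the absorbing screen-positive state.
#' @return An object of class \code{msm_model}.
#' @export
multistate_model <- function(transitions, log_q0, beta = NULL, centers = NULL,
                             states = retinopathy_states(), absorbing = "SP") {
  transitions <- as.matrix(transitions)
  if (ncol(transitions) != 2L)
    stop("`transitions` must have two columns (from, to)")
  storage.mode(transitions) <- "character"
  colnames(transitions) <- c("from", "to")
  if (!all(transitions %in% states))
    stop("transition endpoints must be states of the model")
  if (any(transitions[, "from"] == transitions[, "to"]))
    stop("self-transitions are not allowed")
  if (any(transitions[, "from"] == absorbing))
    stop("the absorbing state admits no outgoing transitions")
  if (length(log_q0) != nrow(transitions))
    stop("one baseline log-intensity per transition is required")
  if (is.null(beta)) beta <- matrix(0, nrow(transitions), 0)
  beta <- as.matrix(beta)
  if (nrow(beta) != nrow(transitions))
    stop("`beta` must have one row per transition")
  if (ncol(beta) > 0 && is.null(colnames(beta)))
    stop("`beta` columns must be named by covariate")
  if (is.null(centers)) centers <- stats::setNames(numeric(ncol(beta)), colnames(beta))
  if (!setequal(names(centers), colnames(beta)))
    stop("`centers` must name exactly the covariates of `beta`")
  structure(
    list(states = states, absorbing = absorbing, transitions = transitions,
         log_q0 = as.numeric(log_q0), beta = beta,
         centers = centers[colnames(beta)]),
    class = "msm_model"
  )
}

#' @export
print.msm_model <- function(x, ...) {
  cat("Continuous-time multi-state model\n")
  cat("  states:", paste(x$states, collapse = " "),
      sprintf("(absorbing: %s)\n", x$absorbing))
  q <- exp(x$log_q0)
  for (i in seq_len(nrow(x$transitions)))
    cat(sprintf("  %s -> %s : q0 = %.5g /month\n",
                x$transitions[i, 1], x$transitions[i, 2], q[i]))
  if (ncol(x$beta) > 0)
    cat("  covariates:", paste(colnames(x$beta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of free parameters of a model
#' @param model an \code{msm_model}.
#' @return Integer count of baseline intensities plus covariate effects.
#' @export
n_parameters <- function(model) {
  length(model$log_q0) + length(model$beta)
}

centre_covariates <- function(model, z) {
  covs <- colnames(model$beta)
  if (length(covs) == 0) return(numeric(0))
  z <- unlist(z)[covs]
  if (anyNA(z) || any(!is.finite(z)))
    stop("non-finite or missing covariate value for: ",
         paste(covs[!is.finite(unlist(z)[covs])], collapse = ", "))
  z - model$centers
}

#' Transition intensity matrix at a covariate vector
#'
#' Evaluates the generator matrix \eqn{Q(z)}: off-diagonal entries are the
#' transition intensities \eqn{q_{rs}(z)} on allowed transitions (zero
#' elsewhere), diagonals are minus the row sums, and the absorbing row is
#' identically zero.
#'
#' @param model an \code{msm_model}.
#' @param z named list or vector of covariate values (ignored for a
#'   covariate-free model).
#' @return Square numeric matrix with dimnames the model states; rows sum
#'   to zero.
#' @export
intensity_matrix <- function(model, z = NULL) {
  zc <- centre_covariates(model, z)
  eta <- model$log_q0
  if (length(zc)) eta <- eta + drop(model$beta %*% zc)
  q <- exp(eta)
  k <- length(model$states)
  Q <- matrix(0, k, k, dimnames = list(model$states, model$states))
  Q[model$transitions] <- q
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over an interval
#'
#' Computes \eqn{P(t) = e^{Qt}} for a generator matrix \eqn{Q}, the matrix
#' of probabilities of occupying each state after \eqn{t} months given the
#' starting state.
#'
#' @param Q generator matrix as returned by \code{\link{intensity_matrix}}.
#' @param t non-negative time in months.
#' @return Row-stochastic matrix of the same dimension as \code{Q}.
#' @export
transition_probabilities <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("`t` must be a single non-negative number of months")
  P <- as.matrix(Matrix::expm(Q * t))
  dimnames(P) <- dimnames(Q)
  # clip tiny negative round-off and renormalise
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Screen-positive risk over a horizon
#'
#' Probability that a participant currently in \code{state}, with covariate
#' vector \code{z}, reaches the absorbing screen-positive state within
#' \code{horizon} months.
#'
#' @inheritParams intensity_matrix
#' @param state current retinopathy state (not the absorbing state).
#' @param horizon horizon in months; the programme uses 6, 12 and 24 but any
#'   non-negative value is accepted.
#' @return Probability in \eqn{[0, 1]}; non-decreasing in \code{horizon}.
#' @export
screen_positive_risk <- function(model, state, z = NULL, horizon) {
  if (state == model$absorbing)
    stop("risk is undefined from the absorbing screen-positive state")
  if (!state %in% model$states) stop("unknown state: ", state)
  Q <- intensity_matrix(model, z)
  P <- transition_probabilities(Q, horizon)
  unname(P[state, model$absorbing])
}

#' Risk profile over the programme horizons
#'
#' @inheritParams screen_positive_risk
#' @param horizons horizons in months (default the programme's 6/12/24).
#' @return Named numeric vector of screen-positive risks, one per horizon.
#' @export
risk_profile <- function(model, state, z = NULL, horizons = c(6, 12, 24)) {
  Q <- intensity_matrix(model, z)
  r <- vapply(horizons, function(h)
    transition_probabilities(Q, h)[state, model$absorbing], numeric(1))
  stats::setNames(r, paste0("risk", horizons))
}

#' Allocate a screening interval against the risk threshold
#'
#' Maps a 6/12/24-month risk profile onto a risk group and recall interval:
#' the longest interval whose cumulative screen-positive risk stays strictly
#' below the threshold wins. Low risk (24 months) if the 24-month risk is
#' below \code{tau}; otherwise medium (12 months) if the 12-month risk is
#' below \code{tau}; otherwise high (6 months). A risk exactly equal to the
#' threshold does not qualify for the longer interval.
#'
#' @param rp risk profile: numeric vector \code{c(risk6, risk12, risk24)}
#'   (named or positional) with non-decreasing entries.
#' @param tau risk threshold, default 0.025 (2.5\%).
#' @return List with \code{group} (\code{"high"}, \code{"medium"} or
#'   \code{"low"}) and \code{interval} (6, 12 or 24 months).
#' @export
allocate_interval <- function(rp, tau = 0.025) {
  rp <- unname(unlist(rp))
  if (length(rp) != 3L || anyNA(rp) || any(rp < 0) || any(rp > 1))
    stop("`rp` must be three probabilities (risk6, risk12, risk24)")
  if (is.unsorted(rp, strict = FALSE))
    stop("risk profile must be non-decreasing in horizon")
  if (rp[3] < tau) {
    list(group = "low", interval = 24)
  } else if (rp[2] < tau) {
    list(group = "medium", interval = 12)
  } else {
    list(group = "high", interval = 6)
  }
}

#' Two-screen stratification rule
#'
#' A simpler comparator rule: allocate a 24-month recall only when neither of
#' the two most recent screens showed any retinopathy in either eye,
#' otherwise 12 months.
#'
#' @param history character vector of the last two observed states, oldest
#'   first; a single state is treated as both screens.
#' @return Recall interval in months (12 or 24).
#' @export
simple_stratification <- function(history) {
  history <- as.character(history)
  if (length(history) < 1L) stop("at least one prior observation is required")
  recent <- utils::tail(history, 2L)
  if (all(recent == "R0R0")) 24 else 12
}
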