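#' @keywords internal
#' Build the consecutive-observation pair table for a panel dataset.
#' Panel columns: id, time (months), state, plus any covariate columns.
.pair_table <- function(data, covariates) {
  ord <- order(data$id, data$time)
  data <- data[ord, , drop = FALSE]
  same <- data$id[-1] == data$id[-nrow(data)]
  i <- which(same)
  dt <- data$time[i + 1L] - data$time[i]
  if (any(dt <= 0)) stop("observation times must be strictly increasing within participant")
  pairs <- data.frame(from = data$state[i], to = data$state[i + 1L], dt = dt,
                      stringsAsFactors = FALSE)
  for (v in covariates) pairs[[v]] <- data[[v]][i]
  pairs
}

#' @keywords internal
#' Log-likelihood of a parameter vector for panel data, caching the
#' transition-probability matrix over unique (covariate row, interval)
#' combinations.
.panel_loglik <- function(theta, skeleton, pairs, covariates, groups = NULL) {
  model <- .theta_to_model(theta, skeleton)
  if (is.null(groups)) groups <- .pair_groups(pairs, covariates)
  ll <- 0
  floorp <- 1e-300
  for (g in groups) {
    Q <- intensity_matrix(model, g$z)
    P <- transition_probabilities(Q, g$dt)
    p <- P[g$cells]
    ll <- ll + sum(log(pmax(p, floorp)) * g$n)
  }
  ll
}

#' @keywords internal
#' Group the pair table by unique (covariate row, interval) combination and,
#' within each, tabulate the (from, to) cells so repeated transitions cost a
#' single probability lookup.
.pair_groups <- function(pairs, covariates) {
  key <- do.call(paste, c(pairs[c("dt", covariates)], sep = "\r"))
  lapply(split(seq_len(nrow(pairs)), key), function(idx) {
    i1 <- idx[1L]
    cell_key <- paste(pairs$from[idx], pairs$to[idx], sep = "\r")
    tab <- table(cell_key)
    ft <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    list(z = if (length(covariates))
           as.list(pairs[i1, covariates, drop = FALSE]) else NULL,
         dt = pairs$dt[i1], cells = ft, n = as.numeric(tab))
  })
}

#' @keywords internal
.theta_to_model <- function(theta, sk) {
  log_q0 <- sk$log_q0_fixed
  log_q0[sk$free_edges] <- theta[seq_along(sk$free_edges)]
  beta <- sk$beta0
  if (length(sk$covariates)) {
    nb <- length(sk$free_edges_beta) * length(sk$covariates)
    beta[sk$free_edges_beta, sk$covariates] <-
      matrix(theta[length(sk$free_edges) + seq_len(nb)],
             nrow = length(sk$free_edges_beta))
  }
  multistate_model(sk$transitions, log_q0, beta, sk$centers,
                   states = sk$states, absorbing = sk$absorbing)
}

#' Fit a covariate-dependent multi-state model to screening panel data
#'
#' Maximum-likelihood fitting for interval-censored panel observations of a
#' continuous-time Markov model. The likelihood of each consecutive pair of
#' observations on a participant is the corresponding entry of the matrix
#' exponential \eqn{P(\Delta t) = e^{Q(z)\Delta t}}, evaluated at the
#' covariates recorded at the start of the interval; the total log-likelihood
#' is maximised numerically (BFGS) over baseline log-intensities and
#' covariate effects.
#'
#' Allowed transitions never observed as a consecutive pair in the data have
#' their baseline intensity pinned to the floor \code{exp(floor_log)} with a
#' warning and are excluded from optimisation. Non-convergence is reported
#' explicitly in the \code{convergence} field, never silently.
#'
#' @param data panel data.frame: \code{id}, \code{time} (months),
#'   \code{state}, plus covariate columns. Each participant's times must be
#'   strictly increasing.
#' @param transitions allowed-transition matrix as for
#'   \code{\link{multistate_model}}.
#' @param covariates character vector of covariate column names (possibly
#'   empty) entering every free transition intensity log-linearly.
#' @param centers named centring constants; defaults to the data means.
#' @param states,absorbing state space, as for \code{\link{multistate_model}}.
#' @param start_log_q0 starting value for baseline log-intensities
#'   (default -3, about 0.05/month).
#' @param floor_log log-intensity assigned to pinned transitions.
#' @param hessian compute the Hessian for Wald standard errors.
#' @param control passed to \code{\link[stats]{optim}}.
#' @return List of class \code{msm_fit}: \code{model} (fitted
#'   \code{msm_model}), \code{loglik}, \code{convergence} (TRUE/FALSE),
#'   \code{theta}, \code{se}, \code{vcov}, \code{pinned},
#'   \code{n_participants}, \code{n_parameters}.
#' @export
fit_multistate_model <- function(data, transitions, covariates = character(0),
                                 centers = NULL,
                                 states = retinopathy_states(), absorbing = "SP",
                                 start_log_q0 = -3, floor_log = -12,
                                 hessian = TRUE,
                                 control = list(maxit = 500, reltol = 1e-10)) {
  transitions <- as.matrix(transitions)
  storage.mode(transitions) <- "character"
  if (nrow(data) < 2L) stop("at least two observations on one participant are required")
  pairs <- .pair_table(data, covariates)
  if (is.null(centers) && length(covariates))
    centers <- vapply(covariates, function(v) mean(data[[v]]), numeric(1))

  observed <- paste(pairs$from, pairs$to)
  pinned <- !(paste(transitions[, 1], transitions[, 2]) %in% observed)
  if (any(pinned))
    warning("no observed transitions for ",
            paste(transitions[pinned, 1], "->", transitions[pinned, 2], collapse = ", "),
            "; intensity pinned to exp(", floor_log, ")")
  free_edges <- which(!pinned)
  if (length(free_edges) == 0L) {
    # no events anywhere: every intensity sits at the floor (the boundary MLE)
    model <- multistate_model(transitions, rep(floor_log, nrow(transitions)),
                              centers = NULL, states = states,
                              absorbing = absorbing)
    ll <- .panel_loglik(numeric(0),
                        list(transitions = transitions, states = states,
                             absorbing = absorbing, covariates = character(0),
                             free_edges = integer(0), free_edges_beta = integer(0),
                             log_q0_fixed = rep(floor_log, nrow(transitions)),
                             beta0 = matrix(0, nrow(transitions), 0),
                             centers = NULL),
                        pairs, character(0))
    return(structure(list(model = model, loglik = ll, convergence = TRUE,
                          theta = numeric(0), se = numeric(0), vcov = NULL,
                          pinned = pinned, transitions = transitions,
                          covariates = character(0),
                          n_participants = length(unique(data$id)),
                          n_parameters = 0L),
                     class = "msm_fit"))
  }

  beta0 <- matrix(0, nrow(transitions), length(covariates),
                  dimnames = list(NULL, covariates))
  skeleton <- list(transitions = transitions, states = states,
                   absorbing = absorbing, covariates = covariates,
                   free_edges = free_edges, free_edges_beta = free_edges,
                   log_q0_fixed = rep(floor_log, nrow(transitions)),
                   beta0 = beta0,
                   centers = if (length(covariates)) centers else NULL)

  theta0 <- c(rep(start_log_q0, length(free_edges)),
              rep(0, length(free_edges) * length(covariates)))
  groups <- .pair_groups(pairs, covariates)
  nll <- function(th) -.panel_loglik(th, skeleton, pairs, covariates, groups)
  opt <- stats::optim(theta0, nll, method = "BFGS", control = control,
                      hessian = hessian)

  theta_names <- c(paste0("logq_", transitions[free_edges, 1], ".",
                          transitions[free_edges, 2]),
                   if (length(covariates))
                     as.vector(outer(paste0("b_", transitions[free_edges, 1], ".",
                                            transitions[free_edges, 2]),
                                     covariates, paste, sep = ":")))
  theta <- stats::setNames(opt$par, theta_names)
  vc <- se <- NULL
  if (hessian) {
    vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    if (!is.null(vc)) {
      dimnames(vc) <- list(theta_names, theta_names)
      se <- sqrt(pmax(diag(vc), 0))
    }
  }
  structure(list(
    model = .theta_to_model(opt$par, skeleton),
    loglik = -opt$value,
    convergence = opt$convergence == 0L,
    theta = theta, se = se, vcov = vc, pinned = pinned,
    transitions = transitions, covariates = covariates,
    n_participants = length(unique(data$id)),
    n_parameters = length(theta)
  ), class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("Multi-state panel fit: logLik = %.3f, %d parameters, %d participants\n",
              x$loglik, x$n_parameters, x$n_participants))
  if (!x$convergence) cat("  WARNING: optimiser did not converge\n")
  est <- data.frame(estimate = x$theta)
  if (!is.null(x$se)) {
    est$se <- x$se
    est$lo95 <- x$theta - stats::qnorm(0.975) * x$se
    est$hi95 <- x$theta + stats::qnorm(0.975) * x$se
  }
  print(round(est, 4))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)} with \eqn{k} free parameters
#' and \eqn{n} participants.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of participants.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Forward covariate selection by corrected AIC
#'
#' Starting from the covariate-free model, repeatedly adds the candidate
#' covariate that most reduces AICc, stopping when no addition improves it.
#' Models whose parameter count reaches the participant count are skipped
#' with a warning.
#'
#' @inheritParams fit_multistate_model
#' @param candidates character vector of candidate covariate columns.
#' @param ... further arguments passed to \code{\link{fit_multistate_model}}
#'   (the selection fits omit Hessians for speed).
#' @return List with \code{selected} (chosen covariate subset),
#'   \code{fit} (the chosen model's \code{msm_fit}) and \code{table}
#'   (data.frame of every model tried: covariates, k, loglik, AICc).
#' @export
aicc_select <- function(data, transitions, candidates, ...) {
  stopifnot(length(candidates) > 0)
  n <- length(unique(data$id))
  tab <- data.frame(covariates = character(), k = integer(),
                    loglik = numeric(), aicc = numeric(),
                    stringsAsFactors = FALSE)
  fit_one <- function(covs) {
    fit <- fit_multistate_model(data, transitions, covariates = covs,
                                hessian = FALSE, ...)
    k <- fit$n_parameters
    if (n <= k + 1) {
      warning("model {", paste(covs, collapse = ","),
              "} skipped: n <= k + 1")
      return(NULL)
    }
    list(fit = fit, k = k, aicc = aicc(fit$loglik, k, n))
  }
  label <- function(covs) if (length(covs)) paste(covs, collapse = "+") else "(none)"

  current <- character(0)
  best <- fit_one(current)
  if (is.null(best)) stop("even the covariate-free model is over-parameterised")
  tab[nrow(tab) + 1L, ] <- list(label(current), best$k, best$fit$loglik, best$aicc)
  remaining <- candidates
  repeat {
    trials <- lapply(remaining, function(v) fit_one(c(current, v)))
    keep <- !vapply(trials, is.null, logical(1))
    trials <- trials[keep]; tried <- remaining[keep]
    if (length(trials) == 0L) break
    for (j in seq_along(trials))
      tab[nrow(tab) + 1L, ] <- list(label(c(current, tried[j])), trials[[j]]$k,
                                    trials[[j]]$fit$loglik, trials[[j]]$aicc)
    aiccs <- vapply(trials, `[[`, numeric(1), "aicc")
    j <- which.min(aiccs)
    if (aiccs[j] >= best$aicc) break
    best <- trials[[j]]
    current <- c(current, tried[j])
    remaining <- setdiff(remaining, tried[j])
    if (length(remaining) == 0L) break
  }
  list(selected = current, fit = best$fit, table = tab)
}
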