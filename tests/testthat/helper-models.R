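# Small fixture models used across test files.

# two observable states + absorbing SP, no covariates
toy_model <- function(q01 = 0.02, q10 = 0.01, q0sp = 0.002, q1sp = 0.01) {
  multistate_model(
    rbind(c("R0R0", "R1R0"), c("R1R0", "R0R0"),
          c("R0R0", "SP"), c("R1R0", "SP")),
    log_q0 = log(c(q01, q10, q0sp, q1sp)),
    states = c("R0R0", "R1R0", "SP")
  )
}

# single R1R1 -> SP transition at a given monthly rate
single_exit_model <- function(q = 0.01) {
  multistate_model(rbind(c("R1R1", "SP")), log_q0 = log(q),
                   states = c("R1R1", "SP"))
}

# one-covariate model for fitting/selection tests (binary covariate keeps
# the likelihood cache small)
cov_model <- function(beta = 0.8) {
  tr <- rbind(c("R0R0", "R1R0"), c("R1R0", "SP"))
  multistate_model(tr, log_q0 = log(c(0.03, 0.02)),
                   beta = matrix(beta, 2, 1, dimnames = list(NULL, "x")),
                   centers = c(x = 0.5),
                   states = c("R0R0", "R1R0", "SP"))
}

# panel with explicit covariate columns drawn by `draw_covs`
simulate_cov_panel <- function(n, model, visit_times, draw_covs, seed = NULL) {
  retscreen:::with_seed(seed, {
    covs <- draw_covs(n)
    rows <- lapply(seq_len(n), function(i) {
      z <- as.list(covs[i, , drop = FALSE])
      path <- sample_progression_path("R0R0", model,
                                      z[colnames(model$beta)],
                                      max(visit_times) + 1)
      s <- path_state_at(path, visit_times)
      sp <- which(s == model$absorbing)
      keep <- if (length(sp)) seq_len(sp[1]) else seq_along(visit_times)
      out <- data.frame(id = i, time = visit_times[keep], state = s[keep])
      for (v in names(covs)) out[[v]] <- covs[[v]][i]
      out
    })
    do.call(rbind, rows)
  })
}

random_valid_model <- function(k_extra_seed) {
  set.seed(k_extra_seed)
  tr <- rbind(c("R0R0", "R1R0"), c("R1R0", "R0R0"), c("R1R0", "R1R1"),
              c("R1R1", "R1R0"), c("R0R0", "SP"), c("R1R0", "SP"),
              c("R1R1", "SP"))
  multistate_model(tr, log_q0 = log(runif(7, 0.0005, 0.05)))
}
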