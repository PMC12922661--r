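# Three-level mean-reverting Hierarchical Gaussian Filter for a
# multi-armed binary bandit, with a volatility-dependent softmax response
# model. Level 1 is the binary feedback of the chosen option, level 2 the
# per-option reward tendency in logit space, level 3 a single log-volatility
# state shared across options. Both latent levels carry AR(1) (mean-reverting)
# dynamics; inference is by precision-weighted prediction errors. Following
# the multi-armed-bandit convention, level-2 uncertainty is common to all
# options (a shared variance); only the means are option-specific. This keeps
# the posterior variance bounded while the means of unchosen options drift
# untouched.

#' HGF parameter set
#'
#' @param mu3_0 Initial level-3 mean: the volatility prior, an individual's
#'   anticipatory expectation of environmental change (unitless
#'   log-volatility).
#' @param sigma3_0 Initial level-3 variance (> 0).
#' @param mu2_0 Initial level-2 mean, shared across options (logit space).
#' @param sigma2_0 Initial level-2 variance (> 0), common to all options.
#' @param kappa Coupling of level-3 volatility into level-2 diffusion (>= 0).
#' @param omega Tonic level-2 log-volatility.
#' @param theta Level-3 innovation variance (>= 0).
#' @param phi2,m2 AR(1) reversion rate in `[0, 1]` and attractor for level 2.
#' @param phi3,m3 AR(1) reversion rate in `[0, 1]` and attractor for level 3.
#' @return An `hgf_params` list.
#' @export
hgf_params <- function(mu3_0 = -3, sigma3_0 = 1, mu2_0 = 0, sigma2_0 = 0.5,
                       kappa = 0.2, omega = -0.5, theta = 0.5,
                       phi2 = 0, m2 = 0, phi3 = 0.02, m3 = -3) {
  p <- list(mu3_0 = mu3_0, sigma3_0 = sigma3_0, mu2_0 = mu2_0,
            sigma2_0 = sigma2_0, kappa = kappa, omega = omega, theta = theta,
            phi2 = phi2, m2 = m2, phi3 = phi3, m3 = m3)
  if (p$sigma3_0 <= 0 || p$sigma2_0 <= 0) stop_config("initial variances must be > 0")
  if (p$kappa < 0 || p$theta < 0) stop_config("kappa and theta must be >= 0")
  if (p$phi2 < 0 || p$phi2 > 1 || p$phi3 < 0 || p$phi3 > 1)
    stop_config("AR(1) rates must lie in [0, 1]")
  structure(p, class = "hgf_params")
}

hgf_param_names <- function() names(hgf_params())

# estimation-space transform per parameter: variance-like -> log,
# rate-like -> logit, means/omega -> identity
hgf_param_space <- function() {
  c(mu3_0 = "id", sigma3_0 = "log", mu2_0 = "id", sigma2_0 = "log",
    kappa = "log", omega = "id", theta = "log",
    phi2 = "logit", m2 = "id", phi3 = "logit", m3 = "id")
}

to_est <- function(x, space) switch(space, id = x, log = log(x), logit = logit(x))
from_est <- function(x, space) switch(space, id = x, log = exp(x), logit = sigm(x))

instability_error <- function(t = NULL) {
  msg <- "non-positive level-3 posterior precision"
  if (!is.null(t)) msg <- paste0(msg, " at trial ", t)
  stop(structure(class = c("metaprl_instability", "error", "condition"),
                 list(message = msg, call = NULL, trial = t)))
}

# ---- filtering core -------------------------------------------------------

hgf_init <- function(params, k) {
  list(mu2 = rep(params$mu2_0, k), sigma2 = params$sigma2_0,
       mu3 = params$mu3_0, sigma3 = params$sigma3_0)
}

# one-step-ahead predictions from the current posterior state
hgf_predict <- function(st, params) {
  xhat2 <- st$mu2 + params$phi2 * (params$m2 - st$mu2)
  xhat3 <- st$mu3 + params$phi3 * (params$m3 - st$mu3)
  v2 <- exp(params$kappa * xhat3 + params$omega)
  list(xhat2 = xhat2, xhat3 = xhat3,
       sigma2hat = st$sigma2 + v2, sigma3hat = st$sigma3 + params$theta,
       mhat = sigm(xhat2), v2 = v2)
}

# posterior update after observing outcome y for chosen option c
hgf_update <- function(st, pred, params, c, y) {
  mhat_c <- pred$mhat[c]
  delta1 <- y - mhat_c
  pihat2 <- 1 / pred$sigma2hat
  pi2 <- pihat2 + mhat_c * (1 - mhat_c)
  mu2 <- pred$xhat2
  mu2[c] <- pred$xhat2[c] + delta1 / pi2
  sigma2 <- 1 / pi2
  # volatility prediction error of the chosen option's level-2 state
  delta2 <- (sigma2 + (mu2[c] - pred$xhat2[c])^2) / pred$sigma2hat - 1
  pihat3 <- 1 / pred$sigma3hat
  w2 <- pred$v2 * pihat2
  pi3 <- pihat3 + (params$kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * delta2)
  if (!is.finite(pi3) || pi3 <= 0) instability_error()
  mu3 <- pred$xhat3 + (params$kappa / 2) * (w2 / pi3) * delta2
  list(mu2 = mu2, sigma2 = sigma2, mu3 = mu3, sigma3 = 1 / pi3,
       delta1 = delta1, delta2 = delta2)
}

#' Forward-filter belief trajectories for an observed session
#'
#' Runs the three-level HGF over a session's choices and outcomes, returning
#' trial-wise predictions, posteriors and prediction errors. Deterministic
#' given inputs.
#'
#' @param session A `prl_session` (see [run_session()]), or any list with a
#'   `records` data frame holding `choice` and `outcome` columns.
#' @param params An [hgf_params()] set.
#' @return An `hgf_trajectory`: per-trial matrices `xhat2`, `mhat`, `mu2`
#'   (trials x options) and vectors `xhat3`, `sigma2`, `mu3`, `sigma3`,
#'   `delta1`, `delta2`, plus the choices/outcomes filtered.
#' @export
filter_beliefs <- function(session, params) {
  stopifnot(inherits(params, "hgf_params"))
  ch <- as.integer(session$records$choice)
  y <- as.integer(session$records$outcome)
  n <- length(ch)
  k <- max(3L, max(ch))
  if (any(y < 0L | y > 1L)) stop_config("outcomes must be binary 0/1")
  xhat2 <- mu2 <- mhat <- matrix(NA_real_, n, k)
  xhat3 <- sigma2 <- mu3 <- sigma3 <- delta1 <- delta2 <- numeric(n)
  st <- hgf_init(params, k)
  for (t in seq_len(n)) {
    pred <- hgf_predict(st, params)
    up <- tryCatch(hgf_update(st, pred, params, ch[t], y[t]),
                   metaprl_instability = function(e) instability_error(t))
    xhat2[t, ] <- pred$xhat2; mhat[t, ] <- pred$mhat
    xhat3[t] <- pred$xhat3
    mu2[t, ] <- up$mu2; sigma2[t] <- up$sigma2
    mu3[t] <- up$mu3; sigma3[t] <- up$sigma3
    delta1[t] <- up$delta1; delta2[t] <- up$delta2
    st <- up[c("mu2", "sigma2", "mu3", "sigma3")]
  }
  structure(list(xhat2 = xhat2, mhat = mhat, xhat3 = xhat3,
                 mu2 = mu2, sigma2 = sigma2, mu3 = mu3, sigma3 = sigma3,
                 delta1 = delta1, delta2 = delta2,
                 choice = ch, outcome = y, params = params),
            class = "hgf_trajectory")
}

#' Volatility-dependent softmax choice probabilities
#'
#' Inverse temperature is `beta = exp(-xhat3)`: decision noise grows with the
#' currently inferred volatility, so agents who expect a changing world choose
#' more stochastically. Uses the pre-outcome prediction of level 3, so a
#' choice never conditions on the outcome it produces.
#'
#' @param mhat Predicted outcome probabilities, one per option.
#' @param xhat3 Predicted level-3 (log-volatility) state at the same trial.
#' @return Choice probabilities (> 0, summing to 1).
#' @export
response_probabilities <- function(mhat, xhat3) {
  beta <- exp(-xhat3)
  z <- beta * mhat
  z <- z - max(z) # overflow guard
  e <- exp(z)
  e / sum(e)
}

#' HGF agent for the PRL environment
#'
#' Wraps the filter and response model into the agent contract used by
#' [run_session()].
#'
#' @param params An [hgf_params()] set.
#' @return An agent list (`init`/`choose`/`update`).
#' @export
hgf_agent <- function(params) {
  force(params)
  list(
    init = function(config) list(hgf = hgf_init(params, config$n_options)),
    choose = function(state, assignment) {
      pred <- hgf_predict(state$hgf, params)
      response_probabilities(pred$mhat, pred$xhat3)
    },
    update = function(state, choice, outcome) {
      pred <- hgf_predict(state$hgf, params)
      up <- hgf_update(state$hgf, pred, params, choice, outcome)
      list(hgf = up[c("mu2", "sigma2", "mu3", "sigma3")])
    }
  )
}

# Inlined closed-loop simulation: identical mathematics (and identical RNG
# consumption) to run_session(hgf_agent(params), ...), kept lean because the
# grid and recovery experiments run tens of thousands of sessions. A
# regression test pins it against the agent-contract route.
hgf_sim_core <- function(params, config, seed, participant_id = "sim") {
  set.seed(as.integer(seed))
  n <- config$n_trials; k <- config$n_options
  phi2 <- params$phi2; m2 <- params$m2
  phi3 <- params$phi3; m3 <- params$m3
  kap <- params$kappa; om <- params$omega; th <- params$theta
  kap2h <- kap^2 / 2
  assignment <- as.numeric(config$probs_pre)
  choice <- integer(n); outcome <- integer(n)
  probs_mat <- matrix(NA_real_, n, k)
  rev_event <- character(n)
  mu2 <- rep(params$mu2_0, k); sigma2 <- params$sigma2_0
  mu3 <- params$mu3_0; sigma3 <- params$sigma3_0
  recent <- integer(n); n_recent <- 0L
  w <- config$perf_window; crit <- config$perf_criterion
  for (t in seq_len(n)) {
    if (t == config$shift_trial)
      assignment <- sort(config$probs_post,
                         decreasing = TRUE)[rank(-assignment, ties.method = "first")]
    # predict
    xhat2 <- mu2 + phi2 * (m2 - mu2)
    xhat3 <- mu3 + phi3 * (m3 - mu3)
    v2 <- exp(kap * xhat3 + om)
    sigma2hat <- sigma2 + v2
    mhat <- 1 / (1 + exp(-xhat2))
    # choose / observe
    z <- exp(-xhat3) * mhat
    e <- exp(z - max(z))
    ch <- sample.int(k, 1L, prob = e / sum(e))
    y <- as.integer(stats::runif(1) < assignment[ch])
    choice[t] <- ch; outcome[t] <- y
    probs_mat[t, ] <- assignment
    # update
    mhat_c <- mhat[ch]
    delta1 <- y - mhat_c
    pihat2 <- 1 / sigma2hat
    pi2 <- pihat2 + mhat_c * (1 - mhat_c)
    mu2 <- xhat2
    mu2[ch] <- xhat2[ch] + delta1 / pi2
    sigma2 <- 1 / pi2
    delta2 <- (sigma2 + (mu2[ch] - xhat2[ch])^2) / sigma2hat - 1
    w2 <- v2 * pihat2
    pi3 <- 1 / (sigma3 + th) + kap2h * w2 * (w2 + (2 * w2 - 1) * delta2)
    if (!is.finite(pi3) || pi3 <= 0) instability_error(t)
    mu3 <- xhat3 + (kap / 2) * (w2 / pi3) * delta2
    sigma3 <- 1 / pi3
    # environment bookkeeping
    n_recent <- n_recent + 1L
    recent[n_recent] <- ch
    ev <- "none"
    if (t %% config$scheduled_period == 0L) {
      ev <- "scheduled"
    } else if (n_recent >= w) {
      best <- which.max(assignment)
      if (sum(recent[(n_recent - w + 1L):n_recent] == best) >= crit)
        ev <- "performance"
    }
    if (ev != "none") {
      assignment <- apply_reversal(assignment)
      n_recent <- 0L
    }
    rev_event[t] <- ev
  }
  records <- data.frame(t = seq_len(n), choice = choice, outcome = outcome)
  colnames(probs_mat) <- paste0("p", seq_len(k))
  records <- cbind(records, probs_mat)
  records$reversal_event <- rev_event
  structure(list(participant_id = participant_id, records = records),
            class = "prl_session")
}

# Lean choice log-likelihood: same filter mathematics without trajectory
# construction. Returns NA on instability.
hgf_filter_ll <- function(ch, y, k, params) {
  n <- length(ch)
  phi2 <- params$phi2; m2 <- params$m2
  phi3 <- params$phi3; m3 <- params$m3
  kap <- params$kappa; om <- params$omega; th <- params$theta
  kap2h <- kap^2 / 2
  mu2 <- rep(params$mu2_0, k); sigma2 <- params$sigma2_0
  mu3 <- params$mu3_0; sigma3 <- params$sigma3_0
  ll <- 0
  for (t in seq_len(n)) {
    xhat2 <- mu2 + phi2 * (m2 - mu2)
    xhat3 <- mu3 + phi3 * (m3 - mu3)
    v2 <- exp(kap * xhat3 + om)
    sigma2hat <- sigma2 + v2
    mhat <- 1 / (1 + exp(-xhat2))
    z <- exp(-xhat3) * mhat
    e <- exp(z - max(z))
    c_t <- ch[t]
    ll <- ll + log(e[c_t] / sum(e))
    mhat_c <- mhat[c_t]
    delta1 <- y[t] - mhat_c
    pihat2 <- 1 / sigma2hat
    pi2 <- pihat2 + mhat_c * (1 - mhat_c)
    mu2 <- xhat2
    mu2[c_t] <- xhat2[c_t] + delta1 / pi2
    sigma2 <- 1 / pi2
    delta2 <- (sigma2 + (mu2[c_t] - xhat2[c_t])^2) / sigma2hat - 1
    w2 <- v2 * pihat2
    pi3 <- 1 / (sigma3 + th) + kap2h * w2 * (w2 + (2 * w2 - 1) * delta2)
    if (!is.finite(pi3) || pi3 <= 0) return(NA_real_)
    mu3 <- xhat3 + (kap / 2) * (w2 / pi3) * delta2
    sigma3 <- 1 / pi3
  }
  ll
}

#' Simulate an HGF agent interacting with the PRL task
#'
#' Closed loop: on each trial the agent's choice is sampled from the
#' volatility-dependent softmax, the outcome is drawn from the task's reward
#' schedule, and beliefs are updated before the next trial, with all reversal
#' and shift logic of the environment applied.
#'
#' @param params An [hgf_params()] set.
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @param participant_id Identifier stored in the session.
#' @param trajectory If `TRUE` (default), also return the belief trajectory
#'   (a refilter of the simulated session); skip it in bulk simulation where
#'   only behavior is needed.
#' @return List with `session` (a `prl_session`) and `trajectory` (an
#'   `hgf_trajectory`, or `NULL` when `trajectory = FALSE`).
#' @export
simulate_agent <- function(params, config, seed, participant_id = "sim",
                           trajectory = TRUE) {
  session <- hgf_sim_core(params, config, seed, participant_id)
  list(session = session,
       trajectory = if (trajectory) filter_beliefs(session, params))
}

# choice log-likelihood of a filtered trajectory under the softmax model
hgf_loglik <- function(traj) {
  n <- length(traj$choice)
  beta <- exp(-traj$xhat3)
  z <- beta * traj$mhat
  z <- z - apply(z, 1, max)
  p <- exp(z)
  p <- p / rowSums(p)
  sum(log(p[cbind(seq_len(n), traj$choice)]))
}

# ---- priors and MAP fitting ----------------------------------------------

#' Parameter priors for MAP inversion
#'
#' Each parameter carries a prior-mean `value` (natural space) and a prior
#' variance `var` in estimation space (log for variance-like, logit for
#' rate-like, identity otherwise). Zero prior variance fixes the parameter
#' during inversion. Defaults ship in
#' `system.file("extdata", "hgf_priors.yaml", package = "metaprl")` and can be
#' replaced wholesale by a user-supplied YAML file of the same structure.
#'
#' @param path YAML file to read; `NULL` loads the packaged defaults.
#' @return An `hgf_priors` named list, one `list(value, var)` per parameter.
#' @export
hgf_priors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hgf_priors.yaml", package = "metaprl")
  raw <- yaml::read_yaml(path)$parameters
  nm <- hgf_param_names()
  if (!all(nm %in% names(raw)))
    stop_config(paste("priors file missing parameters:",
                      paste(setdiff(nm, names(raw)), collapse = ", ")))
  pri <- lapply(raw[nm], function(p) list(value = as.numeric(p$value),
                                          var = as.numeric(p$var)))
  if (any(vapply(pri, function(p) p$var < 0, logical(1))))
    stop_config("prior variances must be >= 0")
  structure(pri, class = "hgf_priors")
}

#' Update selected priors
#'
#' @param priors An `hgf_priors` object.
#' @param ... Named `list(value=, var=)` replacements, e.g.
#'   `mu3_0 = list(value = -2, var = 4)`.
#' @return The modified `hgf_priors`.
#' @export
set_prior <- function(priors, ...) {
  mods <- list(...)
  for (nm in names(mods)) {
    if (!nm %in% names(priors)) stop_config(paste("unknown parameter", nm))
    priors[[nm]] <- utils::modifyList(priors[[nm]], mods[[nm]])
  }
  priors
}

prior_params <- function(priors) {
  do.call(hgf_params, lapply(priors, `[[`, "value"))
}

#' Fit the HGF to one session by MAP estimation
#'
#' Maximizes the sum of the softmax choice log-likelihood and Gaussian
#' log-priors over the free parameters (those with positive prior variance) in
#' unbounded estimation space, by quasi-Newton optimization with jittered
#' restarts. Any filtering instability during an evaluation is absorbed as a
#' large penalty rather than an error; ties between restarts break to the
#' first found.
#'
#' @param session A `prl_session`.
#' @param priors An [hgf_priors()] set.
#' @param n_restarts Number of optimizer starts (first at the prior mean,
#'   the rest jittered by the prior SD).
#' @param seed Integer seed for the restart jitter.
#' @return An `hgf_fit`: list with `params` (MAP [hgf_params()]),
#'   `neg_log_joint`, `loglik`, `convergence` flag and `n_restarts` used.
#' @export
fit_map <- function(session, priors, n_restarts = 10, seed = 1) {
  stopifnot(inherits(priors, "hgf_priors"))
  if (nrow(session$records) < 2L) stop_config("session must have >= 2 trials")
  ch <- as.integer(session$records$choice)
  y <- as.integer(session$records$outcome)
  k <- max(3L, max(ch))
  space <- hgf_param_space()
  free <- names(priors)[vapply(priors, function(p) p$var > 0, logical(1))]
  base <- lapply(priors, `[[`, "value")
  PEN <- 1e10

  make_params <- function(est) {
    vals <- base
    for (i in seq_along(free))
      vals[[free[i]]] <- from_est(est[i], space[[free[i]]])
    do.call(hgf_params, vals)
  }
  est_mean <- vapply(free, function(nm) to_est(base[[nm]], space[[nm]]), 0)
  est_sd <- sqrt(vapply(free, function(nm) priors[[nm]]$var, 0))
  if (any(!is.finite(est_mean)))
    stop_config("a free parameter's prior mean lies on its boundary")

  objective <- function(est) {
    p <- tryCatch(make_params(est), error = function(e) NULL)
    if (is.null(p)) return(PEN)
    ll <- hgf_filter_ll(ch, y, k, p)
    if (is.na(ll) || !is.finite(ll)) return(PEN)
    lp <- sum(stats::dnorm(est, est_mean, est_sd, log = TRUE))
    -(ll + lp)
  }

  if (length(free) == 0L) {
    p <- do.call(hgf_params, base)
    ll <- hgf_filter_ll(ch, y, k, p)
    if (is.na(ll)) stop_config("filtering unstable at the prior means")
    return(structure(list(params = p, neg_log_joint = -ll, loglik = ll,
                          convergence = TRUE, n_restarts = 0L),
                     class = "hgf_fit"))
  }

  set.seed(as.integer(seed))
  starts <- rbind(est_mean,
                  if (n_restarts > 1)
                    matrix(stats::rnorm((n_restarts - 1) * length(free),
                                        mean = rep(est_mean, each = n_restarts - 1),
                                        sd = rep(est_sd, each = n_restarts - 1)),
                           ncol = length(free)))
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[r, ], objective, method = "BFGS",
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= PEN)
    stop_config("all restarts failed or were numerically unstable")
  p <- make_params(best$par)
  ll <- hgf_filter_ll(ch, y, k, p)
  structure(list(params = p, neg_log_joint = best$value, loglik = ll,
                 convergence = best$convergence == 0L,
                 n_restarts = as.integer(n_restarts)),
            class = "hgf_fit")
}

#' @export
print.hgf_fit <- function(x, ...) {
  cat("HGF MAP fit: mu3_0 =", signif(x$params$mu3_0, 4),
      "| -log joint =", signif(x$neg_log_joint, 6),
      "| converged:", x$convergence, "\n")
  invisible(x)
}

#' Export a belief trajectory as a data frame (one row per trial)
#'
#' @param x An `hgf_trajectory`.
#' @param ... Unused.
#' @return A data frame with per-trial predictions, posteriors and errors.
#' @export
as.data.frame.hgf_trajectory <- function(x, ...) {
  k <- ncol(x$mhat)
  out <- data.frame(t = seq_along(x$xhat3), choice = x$choice,
                    outcome = x$outcome)
  for (j in seq_len(k)) {
    out[[paste0("mhat", j)]] <- x$mhat[, j]
    out[[paste0("mu2_", j)]] <- x$mu2[, j]
  }
  out$sigma2 <- x$sigma2
  out$xhat3 <- x$xhat3; out$mu3 <- x$mu3; out$sigma3 <- x$sigma3
  out$delta1 <- x$delta1; out$delta2 <- x$delta2
  out
}
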