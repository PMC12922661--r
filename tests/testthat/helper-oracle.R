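# Independent reference implementation of the three-level mean-reverting
# HGF update equations for a binary multi-armed bandit, written step by step
# from the equations with no code shared with the package internals. Used to
# pin the package filter to the written mathematics.

oracle_filter <- function(choices, outcomes, pars, n_options = 3) {
  n <- length(choices)
  # state
  mu2 <- rep(pars$mu2_0, n_options)
  sig2 <- pars$sigma2_0 # shared across options
  mu3 <- pars$mu3_0
  sig3 <- pars$sigma3_0
  out <- list(mu2 = matrix(NA, n, n_options), sigma2 = numeric(n),
              mu3 = numeric(n), sigma3 = numeric(n),
              xhat2 = matrix(NA, n, n_options), xhat3 = numeric(n),
              mhat = matrix(NA, n, n_options),
              delta1 = numeric(n), delta2 = numeric(n))
  for (t in 1:n) {
    # AR(1) predictions
    xhat2 <- numeric(n_options)
    for (j in 1:n_options) xhat2[j] <- mu2[j] + pars$phi2 * (pars$m2 - mu2[j])
    xhat3 <- mu3 + pars$phi3 * (pars$m3 - mu3)
    # predicted variances
    vol <- exp(pars$kappa * xhat3 + pars$omega)
    sig2hat <- sig2 + vol
    sig3hat <- sig3 + pars$theta
    # predicted outcome probabilities
    mhat <- numeric(n_options)
    for (j in 1:n_options) mhat[j] <- 1 / (1 + exp(-xhat2[j]))
    c_t <- choices[t]
    y <- outcomes[t]
    # level-2 update of the chosen option (binary outcome)
    d1 <- y - mhat[c_t]
    prec2hat <- 1 / sig2hat
    prec2 <- prec2hat + mhat[c_t] * (1 - mhat[c_t])
    new_mu2 <- xhat2
    new_mu2[c_t] <- xhat2[c_t] + d1 / prec2
    new_sig2 <- 1 / prec2
    # level-3 update via the volatility prediction error
    d2 <- (new_sig2 + (new_mu2[c_t] - xhat2[c_t])^2) / sig2hat - 1
    w2 <- vol * prec2hat
    prec3 <- 1 / sig3hat +
      (pars$kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * d2)
    stopifnot(prec3 > 0)
    new_mu3 <- xhat3 + (pars$kappa / 2) * (w2 / prec3) * d2
    new_sig3 <- 1 / prec3
    # record and roll state
    out$xhat2[t, ] <- xhat2; out$xhat3[t] <- xhat3; out$mhat[t, ] <- mhat
    out$mu2[t, ] <- new_mu2; out$sigma2[t] <- new_sig2
    out$mu3[t] <- new_mu3; out$sigma3[t] <- new_sig3
    out$delta1[t] <- d1; out$delta2[t] <- d2
    mu2 <- new_mu2; sig2 <- new_sig2; mu3 <- new_mu3; sig3 <- new_sig3
  }
  out
}

# softmax response probabilities by direct exponentiation-and-normalise
oracle_softmax <- function(mhat, xhat3) {
  b <- exp(-xhat3)
  num <- exp(b * mhat)
  num / sum(num)
}

# build a prl_session object from raw choice/outcome vectors
make_session <- function(choices, outcomes, id = "test") {
  n <- length(choices)
  records <- data.frame(t = seq_len(n), choice = as.integer(choices),
                        outcome = as.integer(outcomes),
                        p1 = 0.9, p2 = 0.5, p3 = 0.1,
                        reversal_event = "none")
  structure(list(participant_id = id, records = records),
            class = "prl_session")
}
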