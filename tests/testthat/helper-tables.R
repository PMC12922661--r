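# Synthetic participant-level tables with known generative coefficients, for
# calibration and coverage checks of the moderation machinery.
# eta = b0 + b1*z1 + b2*z2 + b3*z1*z2 (+ small control effects if given);
# counts are binomial(den, plogis(eta)).
sim_mod_table <- function(n, b0 = -2, b1 = 0, b2 = 0, b3 = 0,
                          b4 = 0, b5 = 0, den = 40) {
  zs <- function(x) (x - mean(x)) / stats::sd(x) # exact sample z-scores
  z1 <- zs(rnorm(n)); z2 <- zs(rnorm(n)); v <- zs(rnorm(n)); g <- zs(rnorm(n))
  eta <- b0 + b1 * z1 + b2 * z2 + b3 * z1 * z2 + b4 * v + b5 * g
  dens <- rep(den, n)
  data.frame(n_win_switches = rbinom(n, dens, stats::plogis(eta)),
             n_win_trials = dens, mu3_0 = z1, M_bar = z2,
             verbosity = v, gcog = g)
}
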