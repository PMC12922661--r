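# Group comparisons and the moderation analysis: a binomial GLM predicting
# win-switch behavior from the volatility prior, metacognitive structure and
# their interaction, with verbosity and general-cognition controls;
# likelihood-ratio tests, odds ratios, average marginal effects, predicted
# probabilities at +/-1 SD, and bootstrap probability-scale contrasts.

#' Z-score a numeric vector
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Values standardized to mean 0, sample SD 1.
#' @export
zscore <- function(values) {
  if (length(unique(values)) < 2L) stop_config("cannot z-score a constant vector")
  (values - mean(values)) / stats::sd(values)
}

# required columns of a moderation table
mod_required <- c("n_win_switches", "n_win_trials", "mu3_0", "M_bar",
                  "verbosity", "gcog")

prepare_mod_frame <- function(table, include_controls) {
  miss <- setdiff(mod_required, names(table))
  if (length(miss) > 0)
    stop_config(paste("moderation table missing columns:",
                      paste(miss, collapse = ", ")))
  drop <- table$n_win_trials == 0
  if (any(drop))
    message(sum(drop), " participant(s) with zero win trials excluded")
  tb <- table[!drop, , drop = FALSE]
  if (nrow(tb) < 10L) stop_config("need >= 10 participants with win trials")
  d <- data.frame(num = tb$n_win_switches, den = tb$n_win_trials,
                  z_mu3 = zscore(tb$mu3_0), z_mp = zscore(tb$M_bar))
  if (include_controls) {
    d$z_verbosity <- zscore(tb$verbosity)
    d$z_gcog <- zscore(tb$gcog)
  }
  d
}

#' Fit the binomial GLM moderation model
#'
#' Models each participant's win-switch behavior as binomial counts
#' (switches out of win trials) with a logit link:
#' `WSR ~ z(mu3_0) + z(M_bar) + z(mu3_0):z(M_bar) + z(V) + z(C)`.
#' All regressors are z-scored across the analysed participants. Participants
#' with zero win trials are excluded (and reported via a message).
#'
#' @param table Data frame with columns `n_win_switches`, `n_win_trials`,
#'   `mu3_0`, `M_bar`, `verbosity`, `gcog`.
#' @param include_interaction Include the `z(mu3_0):z(M_bar)` term.
#' @param include_controls Include verbosity and general-cognition controls.
#' @return A `moderation_fit`: list with the `glm` object, `coefficients`,
#'   `vcov`, `deviance`, `loglik`, the prepared `frame` and the flags.
#' @export
fit_moderation <- function(table, include_interaction = TRUE,
                           include_controls = TRUE) {
  d <- prepare_mod_frame(table, include_controls)
  rhs <- if (include_interaction) "z_mu3 * z_mp" else "z_mu3 + z_mp"
  if (include_controls) rhs <- paste(rhs, "+ z_verbosity + z_gcog")
  fml <- stats::as.formula(paste("cbind(num, den - num) ~", rhs))
  fit <- stats::glm(fml, family = stats::binomial(), data = d)
  if (!fit$converged) stop_config("IRLS did not converge (separation?)")
  structure(list(glm = fit, coefficients = stats::coef(fit),
                 vcov = stats::vcov(fit), deviance = stats::deviance(fit),
                 loglik = as.numeric(stats::logLik(fit)), frame = d,
                 include_interaction = include_interaction,
                 include_controls = include_controls),
            class = "moderation_fit")
}

#' Covariates-only control model
#'
#' Predicts win-switch behavior from verbosity and general cognition alone.
#'
#' @inheritParams fit_moderation
#' @return A `moderation_fit`.
#' @export
fit_covariates_only <- function(table) {
  d <- prepare_mod_frame(table, include_controls = TRUE)
  fit <- stats::glm(cbind(num, den - num) ~ z_verbosity + z_gcog,
                    family = stats::binomial(), data = d)
  structure(list(glm = fit, coefficients = stats::coef(fit),
                 vcov = stats::vcov(fit), deviance = stats::deviance(fit),
                 loglik = as.numeric(stats::logLik(fit)), frame = d,
                 include_interaction = FALSE, include_controls = TRUE),
            class = "moderation_fit")
}

#' Likelihood-ratio test between nested moderation fits
#'
#' @param full,reduced `moderation_fit` objects; `reduced` must be nested in
#'   `full` (its terms a subset of the full model's).
#' @return List with `statistic`, `df`, `p.value`.
#' @export
lrt <- function(full, reduced) {
  t_full <- names(full$coefficients)
  t_red <- names(reduced$coefficients)
  if (!all(t_red %in% t_full) || length(t_full) <= length(t_red))
    stop_config("models are not strictly nested")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-8) stop_config("full model has lower likelihood; not nested fits")
  stat <- max(stat, 0)
  df <- length(t_full) - length(t_red)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Odds ratio with Wald 95% CI for one model term
#'
#' @param fit A `moderation_fit`.
#' @param term Coefficient name (e.g. `"z_mu3"`).
#' @return List with `or`, `ci` (length 2), `p.value`.
#' @export
odds_ratio <- function(fit, term) {
  if (!term %in% names(fit$coefficients)) stop_config("term not in model")
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- stats::qnorm(0.975)
  list(or = exp(b), ci = exp(c(b - z * se, b + z * se)),
       p.value = 2 * stats::pnorm(-abs(b / se)))
}

#' Average marginal effect on the probability scale
#'
#' Mean over observations of `dp/dx = beta * p * (1 - p)` at the fitted
#' probabilities.
#'
#' @param fit A `moderation_fit`.
#' @param term Coefficient name.
#' @return The AME (a probability-scale slope).
#' @export
average_marginal_effect <- function(fit, term) {
  if (!term %in% names(fit$coefficients)) stop_config("term not in model")
  p <- stats::fitted(fit$glm)
  mean(fit$coefficients[[term]] * p * (1 - p))
}

#' Model-predicted win-switch probability at a grid point
#'
#' Evaluates the inverse-logit of the linear predictor at stated z-values of
#' the volatility prior and the metacognition index, with control covariates
#' held at 0 (their z-scored mean).
#'
#' @param fit A `moderation_fit`.
#' @param mu3_z,mp_z Grid point in SD units (typically -1 or +1).
#' @return Predicted probability.
#' @export
predicted_wsr <- function(fit, mu3_z, mp_z) {
  b <- fit$coefficients
  bval <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  eta <- bval("(Intercept)") + bval("z_mu3") * mu3_z + bval("z_mp") * mp_z +
    bval("z_mu3:z_mp") * mu3_z * mp_z
  as.numeric(sigm(eta))
}

# percentage-point rise in predicted WSR from mu3 -1 -> +1 SD at a given MP
pp_rise <- function(fit, mp_z) {
  100 * (predicted_wsr(fit, 1, mp_z) - predicted_wsr(fit, -1, mp_z))
}

#' Bootstrap probability-scale contrast of the moderation effect
#'
#' Quantifies how much the predicted rise in win-switch probability (as the
#' volatility prior goes from -1 to +1 SD) is attenuated at high vs low
#' metacognition: `delta = pp_high - pp_low`, in percentage points.
#' Nonparametric bootstrap resamples participants with replacement, refits the
#' full GLM (with controls) on the original z-scored columns, and recomputes
#' the three quantities; the CI is the percentile 95% interval.
#'
#' @param table Moderation table (see [fit_moderation()]).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param include_controls Include verbosity/cognition controls.
#' @return A `contrast_result`: `pp_low`, `pp_high`, `delta`, `ci` (2-vector),
#'   `boot_delta` (all iterates), `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_contrast <- function(table, n_boot = 1000, seed = 1,
                               include_controls = TRUE) {
  fit0 <- fit_moderation(table, include_interaction = TRUE,
                         include_controls = include_controls)
  d <- fit0$frame
  X <- stats::model.matrix(fit0$glm)
  coef_names <- colnames(X)
  pp_from_coef <- function(b, mp_z) {
    names(b) <- coef_names
    eta <- function(mu3_z) {
      e <- b[["(Intercept)"]] + b[["z_mu3"]] * mu3_z + b[["z_mp"]] * mp_z +
        b[["z_mu3:z_mp"]] * mu3_z * mp_z
      e
    }
    100 * (sigm(eta(1)) - sigm(eta(-1)))
  }
  pp_low <- pp_rise(fit0, -1)
  pp_high <- pp_rise(fit0, 1)
  set.seed(as.integer(seed))
  n <- nrow(d)
  boot_delta <- rep(NA_real_, n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      suppressWarnings(stats::glm.fit(X[idx, , drop = FALSE],
                                      d$num[idx] / d$den[idx],
                                      weights = d$den[idx],
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(res) || !res$converged || anyNA(res$coefficients)) {
      n_failed <- n_failed + 1L
      next
    }
    boot_delta[b] <- pp_from_coef(res$coefficients, 1) -
      pp_from_coef(res$coefficients, -1)
  }
  if (n_failed > 0.05 * n_boot)
    stop_config("more than 5% of bootstrap refits failed")
  ci <- stats::quantile(boot_delta, c(0.025, 0.975), na.rm = TRUE,
                        names = FALSE)
  structure(list(pp_low = pp_low, pp_high = pp_high,
                 delta = pp_high - pp_low, ci = ci, boot_delta = boot_delta,
                 n_boot = n_boot, n_failed = n_failed, seed = seed),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "pp rise (-1 -> +1 SD mu3_0): low MP %+.1f pp, high MP %+.1f pp\n",
    x$pp_low, x$pp_high))
  cat(sprintf("delta = %+.1f pp, bootstrap 95%% CI [%+.1f, %+.1f] (%d iters)\n",
              x$delta, x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' Breusch-Pagan heteroscedasticity test
#'
#' The diagnostic motivating the binomial GLM over OLS: regresses squared OLS
#' residuals on the predictors; LM statistic `n * R^2` with df = number of
#' predictors, plus the companion F form.
#'
#' @param response Numeric response vector.
#' @param predictors Numeric matrix or data frame of predictors.
#' @return List with `statistic`, `df`, `p.value`, `f_statistic`, `f_df`,
#'   `f_p.value`.
#' @export
breusch_pagan <- function(response, predictors) {
  X <- as.matrix(predictors)
  fit <- stats::lm(response ~ X)
  n <- length(response); p <- ncol(X)
  res <- stats::residuals(fit)
  # a (numerically) perfect or constant-residual fit carries no
  # heteroscedasticity signal
  if (stats::var(res^2) == 0 ||
      stats::var(res) < 1e-20 * stats::var(response))
    return(list(statistic = 0, df = p, p.value = 1, f_statistic = 0,
                f_df = c(p, n - p - 1), f_p.value = 1))
  bp <- lmtest::bptest(fit)
  # companion F form from the auxiliary regression R^2
  u2 <- stats::residuals(fit)^2
  aux <- stats::lm(u2 ~ X)
  r2 <- summary(aux)$r.squared
  fstat <- (r2 / p) / ((1 - r2) / (n - p - 1))
  list(statistic = as.numeric(bp$statistic), df = as.numeric(bp$parameter),
       p.value = bp$p.value, f_statistic = fstat, f_df = c(p, n - p - 1),
       f_p.value = stats::pf(fstat, p, n - p - 1, lower.tail = FALSE))
}

#' Two-group Welch comparison or one-way Welch ANOVA
#'
#' For two groups: Welch t-test with pooled-SD Cohen's d. For more than two
#' levels: one-way ANOVA with Welch correction.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of group labels.
#' @return For two groups: list with `t`, `df`, `p.value`, `cohens_d`,
#'   `means`. Otherwise: list with `F`, `df`, `p.value`.
#' @export
group_compare <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) stop_config("each group needs >= 2 values")
  if (nlevels(groups) == 2L) {
    sp <- split(values, groups)
    tt <- stats::t.test(sp[[1]], sp[[2]]) # Welch by default
    n1 <- length(sp[[1]]); n2 <- length(sp[[2]])
    pooled <- sqrt(((n1 - 1) * stats::var(sp[[1]]) +
                      (n2 - 1) * stats::var(sp[[2]])) / (n1 + n2 - 2))
    list(t = as.numeric(tt$statistic), df = as.numeric(tt$parameter),
         p.value = tt$p.value,
         cohens_d = abs(mean(sp[[1]]) - mean(sp[[2]])) / pooled,
         means = vapply(sp, mean, 0))
  } else {
    ow <- stats::oneway.test(values ~ groups)
    list(F = as.numeric(ow$statistic), df = as.numeric(ow$parameter),
         p.value = ow$p.value)
  }
}
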