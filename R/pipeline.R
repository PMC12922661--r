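# End-to-end orchestration. The package's functions are its interface: these
# wrappers chain the stages (simulate -> behavior -> score -> inference ->
# experiments) with one global seed fanned out to every stochastic stage, and
# write tables as CSV and model objects as JSON.

#' Run the full moderation analysis on a participant-level table
#'
#' Group comparisons (WSR, volatility prior, MP index), the binomial GLM with
#' and without the interaction, the likelihood-ratio test of the interaction,
#' odds ratios and average marginal effects for the main effects, predicted
#' win-switch probabilities at the +/-1 SD grid, the bootstrap
#' probability-scale contrast, the Breusch-Pagan diagnostic motivating the
#' GLM, and the covariates-only control model.
#'
#' @param table Cohort table (see [cohort_table()]): needs the moderation
#'   columns plus `wsr` and `group`.
#' @param n_boot Bootstrap iterations for the contrast.
#' @param seed Integer seed.
#' @return An `analysis_bundle` list with elements `group_tests`,
#'   `fit_full`, `fit_no_interaction`, `lrt_interaction`, `odds_ratios`,
#'   `ame`, `predicted`, `contrast`, `breusch_pagan`, `covariates_only`.
#' @export
analyze_table <- function(table, n_boot = 1000, seed = 1) {
  keep <- table$n_win_trials > 0
  tb <- table[keep, , drop = FALSE]
  group_tests <- list(
    wsr = group_compare(tb$wsr, tb$group),
    mu3_0 = group_compare(tb$mu3_0, tb$group),
    M_bar = group_compare(tb$M_bar, tb$group),
    verbosity = group_compare(tb$verbosity, tb$group),
    wsr_performance_cor = stats::cor(tb$wsr, tb$performance)
  )
  fit_full <- fit_moderation(table)
  fit_red <- fit_moderation(table, include_interaction = FALSE)
  lrt_int <- lrt(fit_full, fit_red)
  ors <- list(z_mu3 = odds_ratio(fit_full, "z_mu3"),
              z_mp = odds_ratio(fit_full, "z_mp"))
  ame <- list(z_mu3 = average_marginal_effect(fit_full, "z_mu3"),
              z_mp = average_marginal_effect(fit_full, "z_mp"))
  predicted <- expand.grid(mu3_z = c(-1, 1), mp_z = c(-1, 1))
  predicted$wsr <- mapply(function(a, b) predicted_wsr(fit_full, a, b),
                          predicted$mu3_z, predicted$mp_z)
  contrast <- bootstrap_contrast(table, n_boot = n_boot,
                                 seed = derive_seed(seed, "contrast"))
  bp_covars <- cbind(z_mu3 = zscore(tb$mu3_0), z_mp = zscore(tb$M_bar))
  bp_covars <- cbind(bp_covars, inter = bp_covars[, 1] * bp_covars[, 2],
                     z_verbosity = zscore(tb$verbosity),
                     z_gcog = zscore(tb$gcog))
  bp <- breusch_pagan(tb$wsr, bp_covars)
  cov_only <- fit_covariates_only(table)
  cov_ame <- list(
    z_verbosity = average_marginal_effect(cov_only, "z_verbosity"),
    z_gcog = average_marginal_effect(cov_only, "z_gcog"))
  structure(list(group_tests = group_tests, fit_full = fit_full,
                 fit_no_interaction = fit_red, lrt_interaction = lrt_int,
                 odds_ratios = ors, ame = ame, predicted = predicted,
                 contrast = contrast, breusch_pagan = bp,
                 covariates_only = cov_only, covariates_ame = cov_ame,
                 n_analyzed = nrow(tb)),
            class = "analysis_bundle")
}

#' @export
print.analysis_bundle <- function(x, ...) {
  gt <- x$group_tests
  cat("Participants analysed:", x$n_analyzed, "\n")
  cat(sprintf("group WSR:   t = %.2f, p = %.3g, d = %.2f\n",
              gt$wsr$t, gt$wsr$p.value, gt$wsr$cohens_d))
  cat(sprintf("group mu3_0: t = %.2f, p = %.3g, d = %.2f\n",
              gt$mu3_0$t, gt$mu3_0$p.value, gt$mu3_0$cohens_d))
  cat(sprintf("group M_bar: t = %.2f, p = %.3g, d = %.2f\n",
              gt$M_bar$t, gt$M_bar$p.value, gt$M_bar$cohens_d))
  cat(sprintf("cor(WSR, performance) = %.2f\n", gt$wsr_performance_cor))
  cat(sprintf("OR[z(mu3_0)] = %.2f [%.2f, %.2f]; OR[z(MP)] = %.2f [%.2f, %.2f]\n",
              x$odds_ratios$z_mu3$or, x$odds_ratios$z_mu3$ci[1],
              x$odds_ratios$z_mu3$ci[2], x$odds_ratios$z_mp$or,
              x$odds_ratios$z_mp$ci[1], x$odds_ratios$z_mp$ci[2]))
  cat(sprintf("AME[z(mu3_0)] = %+.3f; AME[z(MP)] = %+.3f\n",
              x$ame$z_mu3, x$ame$z_mp))
  cat(sprintf("LRT interaction: X2(%d) = %.2f, p = %.3g\n",
              x$lrt_interaction$df, x$lrt_interaction$statistic,
              x$lrt_interaction$p.value))
  print(x$contrast)
  invisible(x)
}

#' Serialize an analysis bundle to JSON
#'
#' @param bundle An `analysis_bundle`.
#' @param path Output file.
#' @export
write_analysis_json <- function(bundle, path) {
  f <- bundle$fit_full
  out <- list(
    coefficients = as.list(f$coefficients),
    se = as.list(sqrt(diag(f$vcov))),
    deviance = f$deviance, loglik = f$loglik,
    lrt_interaction = bundle$lrt_interaction,
    odds_ratios = bundle$odds_ratios, ame = bundle$ame,
    predicted = bundle$predicted,
    contrast = bundle$contrast[c("pp_low", "pp_high", "delta", "ci",
                                 "n_boot", "seed")],
    breusch_pagan = bundle$breusch_pagan,
    covariates_ame = bundle$covariates_ame,
    group_tests = bundle$group_tests,
    n_analyzed = bundle$n_analyzed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a cohort and run the complete analysis
#'
#' Convenience wrapper chaining [generate_cohort()], [cohort_table()] and
#' [analyze_table()].
#'
#' @param spec A [cohort_spec()].
#' @param n_boot Bootstrap iterations.
#' @param backend Scorer backend.
#' @param mu3_source Passed to [cohort_table()].
#' @return List with `participants`, `table`, `results`.
#' @export
run_pipeline <- function(spec = cohort_spec(), n_boot = 1000,
                         backend = mp_backend_mock(),
                         mu3_source = "drawn") {
  participants <- generate_cohort(spec)
  table <- cohort_table(participants, backend = backend,
                        mu3_source = mu3_source, seed = spec$seed)
  results <- analyze_table(table, n_boot = n_boot, seed = spec$seed)
  list(participants = participants, table = table, results = results)
}

#' Plot the moderation curves and the probability-scale contrast
#'
#' Base-graphics analogues of the predicted-WSR curves at low/high MP and the
#' pp-contrast bars.
#'
#' @param bundle An `analysis_bundle`.
#' @export
plot_moderation <- function(bundle) {
  fit <- bundle$fit_full
  mu3_grid <- seq(-2, 2, length.out = 50)
  lowc <- vapply(mu3_grid, function(m) predicted_wsr(fit, m, -1), 0)
  highc <- vapply(mu3_grid, function(m) predicted_wsr(fit, m, 1), 0)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(mu3_grid, lowc, type = "l", col = "darkorange", lwd = 2,
                 xlab = "z(mu3_0)", ylab = "predicted WSR",
                 ylim = range(c(lowc, highc)),
                 main = "Predicted win-switch rate")
  graphics::lines(mu3_grid, highc, col = "steelblue", lwd = 2)
  graphics::legend("topleft", c("MP -1 SD", "MP +1 SD"),
                   col = c("darkorange", "steelblue"), lwd = 2, bty = "n")
  ct <- bundle$contrast
  bp <- graphics::barplot(c(low = ct$pp_low, high = ct$pp_high),
                          ylab = "pp rise in WSR (-1 to +1 SD mu3_0)",
                          main = "Probability-scale contrast")
  graphics::text(bp, c(ct$pp_low, ct$pp_high) / 2,
                 sprintf("%+.1f pp", c(ct$pp_low, ct$pp_high)))
  invisible(bundle)
}
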