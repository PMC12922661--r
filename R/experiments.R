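# The two simulation studies: parameter recovery (simulate from fitted
# values, refit, correlate) and the volatility-prior grid experiment mapping
# mu3_0 onto expected win-switch rate, split by metacognition group.

as_params_list <- function(fits) {
  lapply(fits, function(f) {
    if (inherits(f, "hgf_fit")) f$params
    else if (inherits(f, "hgf_params")) f
    else stop_config("fits must be hgf_fit or hgf_params objects")
  })
}

#' Parameter-recovery experiment
#'
#' Treats each participant's parameter set as ground truth, simulates full
#' sessions through the agent-environment loop (reversals, performance
#' triggers and the mid-task contingency shift all active), refits each
#' simulated session with the same priors, and correlates recovered with true
#' values across participants for every free parameter.
#'
#' @param fits List of per-participant `hgf_fit` or [hgf_params()] objects
#'   (>= 10).
#' @param config A [task_config()].
#' @param priors [hgf_priors()] used for refitting.
#' @param n_reps Simulated datasets per participant (default 3).
#' @param seed Integer seed.
#' @param n_restarts Optimizer restarts per refit.
#' @return A `recovery_report`: `table` (participant, rep, true and recovered
#'   values per free parameter, convergence), `correlations` (per free
#'   parameter: `r`, one-sided `p`, `n`), `n_failed`.
#' @export
parameter_recovery <- function(fits, config = task_config(),
                               priors = hgf_priors(), n_reps = 3, seed = 1,
                               n_restarts = 3) {
  params_list <- as_params_list(fits)
  if (length(params_list) < 10L) stop_config("need >= 10 participants")
  free <- names(priors)[vapply(priors, function(p) p$var > 0, logical(1))]
  rows <- list()
  n_failed <- 0L
  for (i in seq_along(params_list)) {
    # key the stage seed to the participant's parameters (not the list
    # position) so the report is invariant to participant order
    pkey <- abs(round(params_list[[i]]$mu3_0 * 1e4)) %% 100000
    for (r in seq_len(n_reps)) {
      s <- derive_seed(seed, "recovery", pkey * 17 + r)
      sim <- simulate_agent(params_list[[i]], config, seed = s)
      fit <- tryCatch(fit_map(sim$session, priors, n_restarts = n_restarts,
                              seed = s),
                      error = function(e) NULL)
      if (is.null(fit)) {
        n_failed <- n_failed + 1L
        next
      }
      row <- data.frame(participant = i, rep = r, converged = fit$convergence)
      for (nm in free) {
        row[[paste0("true_", nm)]] <- params_list[[i]][[nm]]
        row[[paste0("recovered_", nm)]] <- fit$params[[nm]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  correlations <- lapply(free, function(nm) {
    x <- tab[[paste0("true_", nm)]]
    y <- tab[[paste0("recovered_", nm)]]
    if (stats::var(x) == 0)
      return(list(r = NA_real_, p = NA_real_, n = length(x),
                  note = "zero variance in truth"))
    ct <- stats::cor.test(x, y, alternative = "greater")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  })
  names(correlations) <- free
  structure(list(table = tab, correlations = correlations,
                 n_failed = n_failed, n_reps = n_reps, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  for (nm in names(x$correlations)) {
    co <- x$correlations[[nm]]
    cat(sprintf("recovery %s: r = %.3f (one-sided p = %.2g, n = %d)\n",
                nm, co$r, co$p, co$n))
  }
  if (x$n_failed > 0) cat(x$n_failed, "refit(s) failed\n")
  invisible(x)
}

#' Volatility-prior grid experiment (belief-to-behavior mapping)
#'
#' Holds each participant's fitted parameters fixed and sweeps only the
#' initial volatility prior over a grid spanning the 15th-85th percentiles of
#' the empirical mu3_0 distribution; at each grid value full sessions are
#' simulated and the win-switch rate averaged over repetitions, giving a
#' subject-level expected WSR curve. Curves are averaged into a population
#' curve and into low/high metacognition group curves (split at -1/+1 SD of
#' the z-scored MP index), and a linear regression with a group interaction on
#' the two group-mean curves tests whether the belief-behavior slope differs.
#'
#' @param fits List of per-participant `hgf_fit` or [hgf_params()] objects.
#' @param mp_scores Numeric vector of M_bar values, one per participant.
#' @param config A [task_config()].
#' @param n_grid Grid size (default 15).
#' @param pct_lo,pct_hi Percentile span of the grid (defaults 15 and 85).
#' @param n_reps Simulated sessions per participant x grid value
#'   (default 100).
#' @param seed Integer seed.
#' @return A `mapping_curve`: `grid`, `subject_curves` (participants x grid),
#'   `population_curve`, `group_curves` (low/high), `n_low`, `n_high`,
#'   `interaction` (slope difference high - low, its `p.value`, and the two
#'   group slopes).
#' @export
belief_behavior_mapping <- function(fits, mp_scores, config = task_config(),
                                    n_grid = 15, pct_lo = 15, pct_hi = 85,
                                    n_reps = 100, seed = 1) {
  params_list <- as_params_list(fits)
  n <- length(params_list)
  if (length(mp_scores) != n)
    stop_config("mp_scores must match the number of fits")
  mu3 <- vapply(params_list, `[[`, 0, "mu3_0")
  grid <- unname(stats::quantile(mu3, probs = seq(pct_lo, pct_hi,
                                                  length.out = n_grid) / 100,
                                 type = 7)) # linear interpolation
  curves <- matrix(NA_real_, n, n_grid)
  for (i in seq_len(n)) {
    base <- params_list[[i]]
    for (g in seq_len(n_grid)) {
      p <- base
      p$mu3_0 <- grid[g]
      wsr <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        s <- derive_seed(seed, "mapping", (i * 997L + g) * 101L + r)
        sim <- simulate_agent(p, config, seed = s)
        wsr[r] <- win_switch_rate(sim$session)$wsr
      }
      curves[i, g] <- mean(wsr, na.rm = TRUE)
    }
  }
  population <- colMeans(curves)
  z <- zscore(mp_scores)
  low <- z <= -1
  high <- z >= 1
  if (!any(low) || !any(high))
    stop_config("empty low/high MP group at +/-1 SD; relax the split")
  g_low <- colMeans(curves[low, , drop = FALSE])
  g_high <- colMeans(curves[high, , drop = FALSE])
  # interaction test on the two group-mean curves, as group-level regression
  df <- data.frame(wsr = c(g_low, g_high), mu3 = rep(grid, 2),
                   group = rep(c(0, 1), each = n_grid))
  lmfit <- stats::lm(wsr ~ mu3 * group, data = df)
  sm <- summary(lmfit)$coefficients
  structure(list(grid = grid, subject_curves = curves,
                 population_curve = population,
                 group_curves = list(low = g_low, high = g_high),
                 n_low = sum(low), n_high = sum(high),
                 interaction = list(
                   slope_low = unname(stats::coef(lmfit)["mu3"]),
                   slope_high = unname(stats::coef(lmfit)["mu3"] +
                                         stats::coef(lmfit)["mu3:group"]),
                   slope_diff = unname(stats::coef(lmfit)["mu3:group"]),
                   p.value = sm["mu3:group", "Pr(>|t|)"]),
                 n_reps = n_reps, seed = seed),
            class = "mapping_curve")
}

#' @export
print.mapping_curve <- function(x, ...) {
  cat("mu3_0 grid:", length(x$grid), "points in [",
      signif(min(x$grid), 3), ",", signif(max(x$grid), 3), "]\n")
  cat(sprintf("population curve: WSR %.3f -> %.3f (Spearman rho = %.2f)\n",
              x$population_curve[1], x$population_curve[length(x$grid)],
              stats::cor(x$grid, x$population_curve, method = "spearman")))
  cat(sprintf("slopes: low MP %.4f, high MP %.4f (diff %.4f, p = %.3g); n = %d/%d\n",
              x$interaction$slope_low, x$interaction$slope_high,
              x$interaction$slope_diff, x$interaction$p.value,
              x$n_low, x$n_high))
  invisible(x)
}
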