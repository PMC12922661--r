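test_that("z-scoring standardizes to mean 0, sample SD 1", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore(rnorm(50, 3, 2))
  expect_equal(zscore(z), z, tolerance = 1e-12) # idempotent
  expect_error(zscore(rep(2, 10)), "constant")
})

test_that("binomial GLM reproduces closed-form 2x2 log-odds", {
  # two groups of 10 participants; within each group the MP covariate is
  # balanced and carries no effect, so the fit reduces to the 2x2 table:
  # group A 3/10 events, group B 6/10
  tb <- data.frame(
    mu3_0 = rep(c(0, 1), each = 10),
    M_bar = rep(c(0, 1), 10),
    n_win_trials = 10,
    n_win_switches = c(rep(3, 10), rep(6, 10)),
    verbosity = rnorm(20), gcog = rnorm(20))
  f <- fit_moderation(tb, include_interaction = FALSE,
                      include_controls = FALSE)
  sd1 <- stats::sd(tb$mu3_0)
  slope_raw <- f$coefficients[["z_mu3"]] / sd1
  expect_equal(slope_raw, log(3.5), tolerance = 1e-6)
  # intercept at the mid-point of the two groups (z-scored symmetric design)
  expect_equal(f$coefficients[["(Intercept)"]],
               (log(3 / 7) + log(6 / 4)) / 2, tolerance = 1e-6)
  # odds ratio maps back through exp()
  or <- odds_ratio(f, "z_mu3")
  expect_equal(or$or^(1 / sd1), 3.5, tolerance = 1e-6)
})

test_that("coefficients recover generative values within sampling error", {
  set.seed(42)
  hits <- 0L
  n_sims <- 60
  for (i in seq_len(n_sims)) {
    tb <- sim_mod_table(250, b0 = -2, b1 = 0.5, b2 = -0.3, b3 = -0.2)
    f <- fit_moderation(tb, include_controls = FALSE)
    b <- f$coefficients[["z_mu3"]]
    se <- sqrt(f$vcov["z_mu3", "z_mu3"])
    if (abs(b - 0.5) < 2 * se) hits <- hits + 1L
  }
  expect_gte(hits / n_sims, 0.85)
})

test_that("likelihood-ratio test behaves for nested and identical models", {
  set.seed(7)
  tb <- sim_mod_table(200, b1 = 0.4)
  full <- fit_moderation(tb)
  red <- fit_moderation(tb, include_interaction = FALSE)
  out <- lrt(full, red)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 1)
  expect_error(lrt(red, full), "nested")
  expect_error(lrt(full, full), "nested")
  # full-model likelihood dominates the reduced model's
  expect_gte(full$loglik, red$loglik - 1e-10)
})

test_that("a strong simulated interaction is detected with high power", {
  set.seed(11)
  rejections <- 0L
  n_sims <- 30
  for (i in seq_len(n_sims)) {
    tb <- sim_mod_table(480, b1 = 0.5, b2 = -0.3, b3 = -0.3)
    p <- lrt(fit_moderation(tb), fit_moderation(tb, include_interaction = FALSE))$p.value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_sims, 0.8)
})

test_that("odds ratios and AMEs follow their definitions", {
  set.seed(3)
  tb <- sim_mod_table(300, b1 = 0.6)
  f <- fit_moderation(tb)
  or <- odds_ratio(f, "z_mu3")
  expect_equal(or$or, exp(f$coefficients[["z_mu3"]]))
  expect_lt(or$ci[1], or$or); expect_gt(or$ci[2], or$or)
  expect_error(odds_ratio(f, "nope"), "term")
  # AME equals the central finite difference of the mean predicted
  # probability (step 1e-5)
  h <- 1e-5
  X <- stats::model.matrix(f$glm)
  # hold the interaction column fixed: the AME is the partial derivative of
  # the z_mu3 main-effect column only
  shift_main <- function(eps) {
    Xs <- X
    Xs[, "z_mu3"] <- Xs[, "z_mu3"] + eps
    mean(stats::plogis(Xs %*% f$coefficients))
  }
  fd <- (shift_main(h) - shift_main(-h)) / (2 * h)
  expect_equal(average_marginal_effect(f, "z_mu3"), fd, tolerance = 1e-6)
  # beta = 0 gives AME 0
  f0 <- f
  f0$coefficients[["z_mu3"]] <- 0
  expect_equal(average_marginal_effect(f0, "z_mu3"), 0)
})

test_that("predicted probabilities at the +/-1 SD grid match hand arithmetic", {
  hand <- structure(list(coefficients = c("(Intercept)" = -2, z_mu3 = 0.5,
                                          z_mp = 0, "z_mu3:z_mp" = 0)),
                    class = "moderation_fit")
  expect_equal(predicted_wsr(hand, 1, 1), stats::plogis(-1.5))
  expect_equal(predicted_wsr(hand, -1, -1), stats::plogis(-2.5))
  # no interaction: link-scale slope identical at low and high MP
  expect_equal(stats::qlogis(predicted_wsr(hand, 1, 1)) -
                 stats::qlogis(predicted_wsr(hand, -1, 1)),
               stats::qlogis(predicted_wsr(hand, 1, -1)) -
                 stats::qlogis(predicted_wsr(hand, -1, -1)))
  # intercept-only model is flat
  flat <- structure(list(coefficients = c("(Intercept)" = -1)),
                    class = "moderation_fit")
  expect_equal(predicted_wsr(flat, 1, -1), stats::plogis(-1))
  expect_equal(predicted_wsr(flat, -1, 1), stats::plogis(-1))
})

test_that("probability-scale contrasts bend without any interaction term", {
  # with b3 = 0 but b2 != 0 the logit-scale rise is constant, yet the
  # probability-scale rise differs between MP levels
  hand <- structure(list(coefficients = c("(Intercept)" = -2, z_mu3 = 0.8,
                                          z_mp = -0.7, "z_mu3:z_mp" = 0)),
                    class = "moderation_fit")
  pp_low <- 100 * (predicted_wsr(hand, 1, -1) - predicted_wsr(hand, -1, -1))
  pp_high <- 100 * (predicted_wsr(hand, 1, 1) - predicted_wsr(hand, -1, 1))
  expect_false(isTRUE(all.equal(pp_low, pp_high)))
})

test_that("bootstrap contrasts are reproducible and carry percentile CIs", {
  set.seed(13)
  tb <- sim_mod_table(150, b1 = 0.5, b2 = -0.3, b3 = -0.25)
  c1 <- bootstrap_contrast(tb, n_boot = 120, seed = 9)
  c2 <- bootstrap_contrast(tb, n_boot = 120, seed = 9)
  expect_identical(c1$boot_delta, c2$boot_delta)
  expect_identical(c1$ci, c2$ci)
  expect_lte(c1$ci[1], stats::median(c1$boot_delta, na.rm = TRUE))
  expect_gte(c1$ci[2], stats::median(c1$boot_delta, na.rm = TRUE))
  expect_equal(c1$delta, c1$pp_high - c1$pp_low)
})

test_that("a strong negative interaction yields negative, significant deltas", {
  set.seed(19)
  neg <- 0L
  n_meta <- 20
  for (i in seq_len(n_meta)) {
    tb <- sim_mod_table(250, b1 = 0.6, b2 = -0.3, b3 = -0.4)
    ct <- bootstrap_contrast(tb, n_boot = 150, seed = i)
    if (ct$delta < 0 && ct$ci[2] < 0) neg <- neg + 1L
  }
  expect_gte(neg / n_meta, 0.8)
})

test_that("Breusch-Pagan detects variance growing with a predictor", {
  set.seed(23)
  hits <- 0L
  n_sims <- 40
  for (i in seq_len(n_sims)) {
    x <- rnorm(500)
    y <- 1 + x + rnorm(500, sd = exp(0.4 * x)) # variance monotone in x
    if (breusch_pagan(y, cbind(x))$p.value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_sims, 0.9)
  # perfectly constant residuals give a zero statistic
  xx <- 1:20
  out <- breusch_pagan(2 * xx + 3, cbind(xx))
  expect_equal(out$statistic, 0)
})

test_that("group comparisons return Welch t, pooled d, and Welch ANOVA", {
  x <- c(1, 2, 3, 4); g <- c("a", "a", "b", "b")
  same <- group_compare(c(x, x), rep(c("a", "b"), each = 4))
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p.value, 1)
  set.seed(29)
  v <- c(rnorm(1000, 0), rnorm(1000, 1))
  gg <- rep(c("lo", "hi"), each = 1000)
  out <- group_compare(v, gg)
  expect_true(out$cohens_d > 0.85 && out$cohens_d < 1.15)
  aov3 <- group_compare(c(rnorm(20), rnorm(20, 2), rnorm(20)),
                        rep(c("a", "b", "c"), each = 20))
  expect_true(all(c("F", "p.value") %in% names(aov3)))
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")), ">= 2")
})
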