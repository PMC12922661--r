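test_that("expected score is the probability-weighted rubric level", {
  expect_equal(expected_score(c(0.1, 0.2, 0.3, 0.2, 0.2)), 2.2)
  expect_equal(expected_score(c(1, 0, 0, 0, 0)), 0.0)
  expect_equal(expected_score(c(0, 0, 0, 0, 1)), 4.0)
})

test_that("expected score is linear in the distribution", {
  set.seed(8)
  for (i in 1:20) {
    p <- as.vector(stats::rgamma(5, 1)); p <- p / sum(p)
    q <- as.vector(stats::rgamma(5, 1)); q <- q / sum(q)
    lam <- runif(1)
    expect_equal(expected_score(lam * p + (1 - lam) * q),
                 lam * expected_score(p) + (1 - lam) * expected_score(q),
                 tolerance = 1e-12)
  }
})

test_that("malformed distributions are renormalized or rejected", {
  slightly_off <- c(0.1, 0.2, 0.3, 0.2, 0.2005) # off by 5e-4
  expect_equal(sum(metaprl:::validate_dist(slightly_off)), 1, tolerance = 1e-12)
  expect_error(expected_score(c(0.5, 0.5, 0.5, 0, 0)), "sum to 1")
  expect_error(expected_score(c(0.5, 0.5, -0.1, 0.05, 0.05)), "non-negative")
})

test_that("mean MP score averages the five dimensions", {
  expect_equal(mean_mp(c(2, 2, 2, 2, 2)), 2.0)
  expect_equal(mean_mp(c(0, 1, 2, 3, 4)), 2.0)
  expect_equal(mean_mp(c(2.2, 1.0, 3.0, 0.5, 1.3)), 1.6)
  expect_error(mean_mp(c(1, 2, 3)), "five")
})

test_that("short reflections auto-score zero on every dimension", {
  for (txt in c("", "ok", "   no   ")) {
    sc <- score_reflection(reflection("p", txt))
    expect_equal(unname(sc$M_d), rep(0, 5))
    expect_equal(sc$M_bar, 0)
    expect_equal(sc$distributions[[1]], c(1, 0, 0, 0, 0))
  }
})

test_that("the mock backend is deterministic and monotone in structure", {
  be <- mp_backend_mock()
  rich <- paste("I picked the deck that gave the most points.",
                "I noticed a pattern and counted how long streaks lasted.",
                "Switching early did not work, so staying longer worked better.",
                "I decided on a rule and usually stuck with it.",
                "I was fairly sure about my approach though I took risks.")
  sparse <- "I picked whatever card looked good."
  s_rich <- score_reflection(reflection("a", rich), be)
  s_sparse <- score_reflection(reflection("b", sparse), be)
  expect_gt(s_rich$M_bar, s_sparse$M_bar)
  expect_identical(score_reflection(reflection("a", rich), be)$distributions,
                   s_rich$distributions)
  # adding an evaluative clause never lowers any dimension score
  plus_eval <- paste(sparse, "That approach worked better than expected.")
  s_plus <- score_reflection(reflection("c", plus_eval), be)
  expect_true(all(s_plus$M_d >= s_sparse$M_d - 1e-12))
})

test_that("backend contract violations are surfaced", {
  bad <- function(text) rep(list(c(0.3, 0.3, 0.3, 0.3, 0.3)), 5)
  expect_error(score_reflection(reflection("p", strrep("words here ", 5)), bad),
               "sum to 1")
  wrong_n <- function(text) rep(list(c(1, 0, 0, 0, 0)), 3)
  expect_error(score_reflection(reflection("p", strrep("words here ", 5)),
                                wrong_n), "five")
})

test_that("CRT scoring accepts numeric, text and unit variants", {
  r <- score_crt(c("0.05", "5 minutes", "47"))
  expect_equal(r$items, c(1L, 1L, 1L))
  expect_equal(r$accuracy, 1.0)
  r2 <- score_crt(c("10 cents", "100 minutes", "24"))
  expect_equal(r2$items, c(0L, 0L, 0L))
  expect_equal(r2$accuracy, 0.0)
  expect_equal(score_crt(c("", "", ""))$accuracy, 0.0)
  expect_equal(score_crt(c("5 cents", "five", "forty-seven"))$items,
               c(1L, 1L, 1L))
  expect_equal(score_crt(c("$0.05", "5", "47 days"))$items, c(1L, 1L, 1L))
  expect_equal(score_crt(c("five", "5 hours", "47 minutes"))$items,
               c(0L, 0L, 0L))
})

test_that("general cognition is the literal two-scale average", {
  expect_equal(general_cognition(8, 1.0), 4.5)
  expect_equal(general_cognition(1, 0.0), 0.5)
  expect_equal(general_cognition(4, 2 / 3), 7 / 3)
  expect_error(general_cognition(0, 0.5), "1..8")
  expect_error(general_cognition(3.5, 0.5), "1..8")
})

test_that("ICC matches a from-scratch variance-components oracle", {
  # hand ANOVA decomposition on a 4 x 2 toy table
  m <- matrix(c(9, 6, 8, 7, 2, 1, 4, 1), 4, 2)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sst <- sum((m - grand)^2)
  mse <- (sst - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  icc21 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc2k <- (msr - mse) / (msr + (msc - mse) / n)
  expect_equal(icc(m, "single"), icc21, tolerance = 1e-12)
  expect_equal(icc(m, "average"), icc2k, tolerance = 1e-12)
  expect_gte(icc(m, "average"), icc(m, "single"))
})

test_that("ICC is 1 for perfect agreement and ~0 for independent raters", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc(m, "single"), 1.0)
  set.seed(5)
  null_m <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc(null_m, "single")), 0.15)
  expect_warning(v <- icc(matrix(3, 4, 2)), "constant")
  expect_true(is.na(v))
})
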