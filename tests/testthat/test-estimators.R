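test_that("OLS interpolates noiseless linear data and balances the mean", {
  df <- make_linear_df(30, seed = 1)
  f <- fit_ols(chu9d ~ x, df)
  expect_equal(unname(coef(f)), c(2, 3), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # with an intercept, mean(fitted) = mean(y) on any input
  df2 <- make_linear_df(57, seed = 2, noise_sd = 0.8)
  f2 <- fit_ols(chu9d ~ x, df2)
  expect_equal(mean(f2$fitted), mean(df2$chu9d), tolerance = 1e-12)
})

test_that("OLS HC1 sandwich matches the reference implementation", {
  skip_if_not_installed("sandwich")
  set.seed(3)
  df <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  df$chu9d <- 1 + 0.5 * df$x1 - 0.2 * df$x2 + rnorm(80) * (1 + abs(df$x1))
  f <- fit_ols(chu9d ~ x1 + x2, df)
  lmfit <- stats::lm(chu9d ~ x1 + x2, df)
  expect_equal(unname(coef(f)), unname(coef(lmfit)), tolerance = 1e-10)
  ref <- sqrt(diag(sandwich::vcovHC(lmfit, type = "HC1")))
  expect_equal(unname(f$se), unname(ref), tolerance = 1e-8)
})

test_that("rank-deficient designs are refused with the collinear term named", {
  df <- make_linear_df(20, seed = 4, noise_sd = 0.1)
  df$x_dup <- df$x
  expect_error(fit_ols(chu9d ~ x + x_dup, df), "x_dup")
})

test_that("fractional logit reproduces closed forms and the mean identity", {
  # constant response: intercept = logit(0.7), slope exactly 0
  set.seed(5)
  df <- data.frame(chu9d = rep(0.7, 40), x = rnorm(40))
  f <- fit_fractional_logit(chu9d ~ x, df)
  expect_equal(unname(coef(f)), c(stats::qlogis(0.7), 0), tolerance = 1e-8)
  # canonical-link score equation: fitted mean equals observed mean
  for (s in 1:4) {
    set.seed(s)
    d2 <- data.frame(x = rnorm(60))
    d2$chu9d <- pmin(pmax(stats::plogis(1 + d2$x) + rnorm(60, 0, 0.05), 0.05), 1)
    f2 <- fit_fractional_logit(chu9d ~ x, d2)
    expect_lt(abs(mean(f2$fitted) - mean(d2$chu9d)), 1e-8)
  }
})

test_that("fractional logit agrees with the quasi-binomial reference fit", {
  set.seed(6)
  df <- data.frame(x1 = rnorm(120), x2 = rnorm(120))
  df$chu9d <- pmin(pmax(stats::plogis(0.8 + 0.5 * df$x1 - 0.3 * df$x2) +
                          rnorm(120, 0, 0.08), 0.02), 1)
  f <- fit_fractional_logit(chu9d ~ x1 + x2, df)
  ref <- suppressWarnings(
    stats::glm(chu9d ~ x1 + x2, family = stats::quasibinomial(), data = df))
  expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-7)
  skip_if_not_installed("sandwich")
  ref_se <- sqrt(diag(sandwich::sandwich(ref)))
  expect_equal(unname(f$se), unname(ref_se), tolerance = 1e-6)
})

test_that("fractional logit refuses responses outside (0, 1]", {
  df <- data.frame(chu9d = c(0.5, 0, 0.7), x = 1:3)
  expect_error(fit_fractional_logit(chu9d ~ x, df), "\\(0, 1\\]")
  df$chu9d <- c(0.5, 1.2, 0.7)
  expect_error(fit_fractional_logit(chu9d ~ x, df), "\\(0, 1\\]")
})

test_that("record order does not move deterministic estimators", {
  df <- make_linear_df(45, seed = 7, noise_sd = 0.5)
  df$chu9d <- pmin(pmax(stats::plogis(df$chu9d / 4), 0.05), 0.99)
  perm <- sample(nrow(df))
  for (fitter in list(fit_ols, fit_fractional_logit)) {
    f1 <- fitter(chu9d ~ x, df)
    f2 <- fitter(chu9d ~ x, df[perm, ])
    expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  }
})
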