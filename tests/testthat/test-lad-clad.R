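test_that("LAD interpolates two points and returns the lower median", {
  df <- data.frame(chu9d = c(1, 3), x = c(0, 2))
  f <- fit_lad(chu9d ~ x, df, se = "none")
  expect_equal(unname(coef(f)), c(1, 1), tolerance = 1e-12)
  expect_equal(f$convergence$objective, 0, tolerance = 1e-12)

  # intercept-only: lower median under even-n ties, median when odd
  expect_equal(unname(coef(fit_lad(chu9d ~ 1, data.frame(chu9d = c(1, 2, 3, 10)),
                                   se = "none"))), 2)
  expect_equal(unname(coef(fit_lad(chu9d ~ 1, data.frame(chu9d = c(5, 1, 9, 2, 7)),
                                   se = "none"))), 5)
})

test_that("LAD attains the brute-force LP optimum on small instances", {
  for (s in 1:6) {
    df <- make_linear_df(15, seed = s, b0 = 0.5, b1 = 1.5, noise_sd = 0.5,
                         noise = "cauchy")
    f <- fit_lad(chu9d ~ x, df, se = "none")
    oracle <- brute_force_lad_objective(cbind(1, df$x), df$chu9d)
    expect_lt(abs(f$convergence$objective - oracle), 1e-8)
  }
  # three-parameter instance
  set.seed(99)
  df <- data.frame(x1 = rnorm(12), x2 = rnorm(12))
  df$chu9d <- 1 - df$x1 + 0.5 * df$x2 + rcauchy(12) * 0.3
  f <- fit_lad(chu9d ~ x1 + x2, df, se = "none")
  oracle <- brute_force_lad_objective(cbind(1, df$x1, df$x2), df$chu9d)
  expect_lt(abs(f$convergence$objective - oracle), 1e-8)
})

test_that("LAD objective never exceeds the OLS absolute-error objective", {
  for (s in 1:5) {
    df <- make_linear_df(40, seed = s, noise_sd = 1, noise = "cauchy")
    flad <- fit_lad(chu9d ~ x, df, se = "none")
    fols <- fit_ols(chu9d ~ x, df)
    expect_lte(flad$convergence$objective,
               sum(abs(df$chu9d - fols$fitted)) + 1e-10)
  }
})

test_that("LAD is invariant to record order", {
  df <- make_linear_df(35, seed = 8, noise_sd = 0.7)
  set.seed(1)
  f1 <- fit_lad(chu9d ~ x, df, se = "none")
  f2 <- fit_lad(chu9d ~ x, df[sample(35), ], se = "none")
  expect_equal(f1$convergence$objective, f2$convergence$objective,
               tolerance = 1e-10)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("CLAD equals LAD exactly when censoring is inactive", {
  df <- make_linear_df(50, seed = 9, b0 = 0.2, b1 = 0.05, noise_sd = 0.05)
  expect_true(all(df$chu9d < 1))
  fc <- fit_clad(chu9d ~ x, df, upper_censor = 1, se = "none")
  fl <- fit_lad(chu9d ~ x, df, se = "none")
  expect_identical(unname(coef(fc)), unname(coef(fl)))
  expect_identical(fc$retained, seq_len(50L))
})

test_that("CLAD trims ceiling observations and beats OLS under censoring", {
  df <- make_censored_df(400, seed = 10)
  fc <- fit_clad(chu9d ~ x, df, se = "none")
  fo <- fit_ols(chu9d ~ x, df)
  expect_lt(length(fc$retained), 400)
  expect_lt(abs(coef(fc)[["x"]] - 0.5), abs(coef(fo)[["x"]] - 0.5))
  # deterministic given data order: identical refits
  fc2 <- fit_clad(chu9d ~ x, df, se = "none")
  expect_identical(coef(fc), coef(fc2))
})

test_that("CLAD errors on degenerate censoring input", {
  df <- data.frame(chu9d = rep(1, 20), x = rnorm(20))
  expect_error(fit_clad(chu9d ~ x, df), "below the censor point")
})

test_that("bootstrap standard errors are positive and finite", {
  df <- make_censored_df(80, seed = 12)
  f <- fit_clad(chu9d ~ x, df, se = "bootstrap", B = 30, seed = 4)
  expect_true(all(is.finite(f$se)) && all(f$se > 0))
  expect_true(all(is.finite(f$p_values)))
  # seeded: same seed reproduces the SEs
  f2 <- fit_clad(chu9d ~ x, df, se = "bootstrap", B = 30, seed = 4)
  expect_identical(f$se, f2$se)
})
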