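test_that("goodness of fit computes MAE/RMSE and the truncation variants", {
  y <- c(0.5, 0.7, 0.9)
  expect_equal(gof(y, y)$mae, 0)
  expect_equal(gof(y, y)$rmse, 0)
  g <- gof(c(0.5, 0.7), c(0.6, 0.6))       # errors +0.1, -0.1
  expect_equal(g$mae, 0.1)
  expect_equal(g$rmse, 0.1)
  g2 <- gof(c(0.5, 0.5), c(0.5, 0.7))      # errors 0, 0.2
  expect_equal(g2$mae, 0.1)
  expect_equal(g2$rmse, sqrt(0.02), tolerance = 1e-12)
  expect_error(gof(1:3, 1:2), "equal length")
})

test_that("MAE never exceeds RMSE, with equality iff equal-magnitude errors", {
  set.seed(20)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    g <- gof(runif(n), runif(n, 0, 1.3))
    expect_lte(g$mae, g$rmse + 1e-12)
  }
  g <- gof(c(0.4, 0.8), c(0.5, 0.7))  # |errors| all 0.1
  expect_equal(g$mae, g$rmse)
})

test_that("truncation at one never worsens MAE or RMSE when y <= 1", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    y <- runif(n, 0.33, 1)
    pred <- y + rnorm(n, 0.05, 0.2)    # over-predictions push past 1
    g <- gof(y, pred)
    expect_lte(g$mae_trunc, g$mae + 1e-12)
    expect_lte(g$rmse_trunc, g$rmse + 1e-12)
    expect_true(all(abs(pmin(pred, 1) - y) <= abs(pred - y) + 1e-15))
  }
})

test_that("VIFs are one for orthogonal terms and closed-form under correlation", {
  n <- 100
  set.seed(22)
  z1 <- scale(rnorm(n))[, 1]
  z2 <- scale(stats::resid(stats::lm(rnorm(n) ~ z1)))[, 1]  # exactly orthogonal
  d <- data.frame(a = z1, b = z2)
  v <- vif(d, c("a", "b"))
  expect_equal(unname(v$vif), c(1, 1), tolerance = 1e-10)
  # exact sample correlation 0.6: VIF = 1/(1-0.36)
  d$c <- 0.6 * z1 + 0.8 * z2
  v2 <- vif(d, c("a", "c"))
  expect_equal(unname(v2$vif), c(1.5625, 1.5625), tolerance = 1e-10)
  # duplicated column: infinite VIF reported, not an error
  d$a2 <- d$a
  v3 <- vif(d, c("a", "a2", "b"))
  expect_true(is.infinite(v3$vif[["a"]]) && is.infinite(v3$vif[["a2"]]))
})

test_that("forward stepwise honours the entry threshold and tie rule", {
  set.seed(23)
  n <- 200
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  df$chu9d <- 0.5 + 1 * df$x1 + rnorm(n, 0, 0.5)
  # p_enter = 0 excludes everything
  s0 <- forward_stepwise(df, candidates = c("x1", "x2", "x3"), p_enter = 0)
  expect_identical(s0$selected, character(0))
  # noiseless single predictor is certain to enter
  df2 <- data.frame(x1 = rnorm(n))
  df2$chu9d <- 1 + 2 * df2$x1
  s1 <- forward_stepwise(df2, candidates = "x1")
  expect_identical(s1$selected, "x1")
  # duplicated candidate columns: the earlier candidate wins the tie
  df$x1b <- df$x1
  s2 <- forward_stepwise(df, candidates = c("x1", "x1b"))
  expect_identical(s2$selected[1], "x1")
  expect_true(all(s2$trace$p_value < 0.05))
})

test_that("bootstrap stepwise counts are bounded and certain under no noise", {
  set.seed(24)
  df <- data.frame(x1 = rnorm(50))
  df$chu9d <- 1 + 2 * df$x1
  b1 <- bootstrap_stepwise(df, candidates = "x1", B = 1, seed = 1)
  expect_true(all(b1$counts %in% c(0L, 1L)))
  b2 <- bootstrap_stepwise(df, candidates = "x1", B = 10, seed = 1)
  expect_identical(unname(b2$counts), 10L)
  # reproducible from the seed
  b3 <- bootstrap_stepwise(df, candidates = "x1", B = 10, seed = 1)
  expect_identical(b2$counts, b3$counts)
})
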