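# Fixtures built in code: small regression datasets and brute-force oracles.

item_names <- names(chu9dmap::ks_items())

# One-row data frame with every item at `level`.
all_items_row <- function(level = 5L) {
  as.data.frame(as.list(stats::setNames(rep(level, 10), item_names)))
}

# Simple linear-regression data: y = b0 + b1 * x + noise.
make_linear_df <- function(n, seed, b0 = 2, b1 = 3, noise_sd = 0,
                           noise = c("gaussian", "cauchy")) {
  noise <- match.arg(noise)
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- if (noise_sd == 0) 0
       else if (noise == "gaussian") stats::rnorm(n, 0, noise_sd)
       else stats::rcauchy(n) * noise_sd
  data.frame(chu9d = b0 + b1 * x + e, x = x)
}

# Brute-force LAD oracle: the optimum interpolates p observations, so
# enumerate every p-subset, solve it exactly, and take the smallest
# sum of absolute residuals (n small).
brute_force_lad_objective <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  best <- Inf
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    b <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                  error = function(e) NULL)
    if (is.null(b)) next
    best <- min(best, sum(abs(y - as.numeric(X %*% b))))
  }
  best
}

# Ceiling-censored simple regression emulating utilities piling up at 1:
# latent y* = 0.3 + 0.5 x with Gaussian noise, observed y = min(y*, 1).
make_censored_df <- function(n, seed, noise_sd = 0.1) {
  set.seed(seed)
  x <- stats::runif(n, 0, 2)
  ystar <- 0.3 + 0.5 * x + stats::rnorm(n, 0, noise_sd)
  data.frame(chu9d = pmin(ystar, 1), x = x)
}
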