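# Shared estimation infrastructure: design construction, the chu9d_fit
# container, and the two likelihood-free workhorses (OLS with HC1 sandwich
# SEs, fractional logit with the GLM sandwich).

build_design <- function(formula, data, allow_exact = FALSE) {
  mf <- stats::model.frame(formula, data = as.data.frame(data),
                           na.action = stats::na.fail)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X)
  if (n < p + !allow_exact) {
    stop("need more records than parameters (n = ", n, ", p = ", p, ")")
  }
  qx <- qr(X)
  if (qx$rank < p) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design is rank deficient; collinear term(s): ",
         paste(drop_cols, collapse = ", "))
  }
  list(X = X, y = y, terms = stats::terms(mf), qr = qx)
}

new_chu9d_fit <- function(coefficients, se, fitted, residuals, estimator,
                          se_type, convergence, terms, n,
                          r_squared = NULL, scale = NULL, retained = NULL) {
  p_values <- 2 * stats::pnorm(-abs(coefficients / se))
  structure(list(coefficients = coefficients, se = se, p_values = p_values,
                 fitted = fitted, residuals = residuals,
                 estimator = estimator, se_type = se_type,
                 convergence = convergence, terms = terms, n = n,
                 p = length(coefficients), r_squared = r_squared,
                 scale = scale, retained = retained),
            class = "chu9d_fit")
}

#' @export
print.chu9d_fit <- function(x, ...) {
  cat(x$estimator, "fit on", x$n, "records (", x$p, "parameters ), SE type:",
      x$se_type, "\n")
  tab <- cbind(Estimate = x$coefficients, `Robust SE` = x$se,
               `p value` = x$p_values)
  print(tab)
  if (!is.null(x$r_squared)) cat("R-squared:", format(x$r_squared, digits = 4), "\n")
  if (!isTRUE(x$convergence$converged)) cat("WARNING: estimator did not converge\n")
  invisible(x)
}

#' @export
coef.chu9d_fit <- function(object, ...) object$coefficients

#' Predict from a fitted mapping model
#'
#' Evaluates the fitted equation on new records: the linear predictor for
#' OLS/LAD/CLAD/MM fits, the inverse-logit of the linear predictor for
#' fractional-logit fits.
#'
#' @param object A `chu9d_fit`.
#' @param newdata Data frame carrying the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions (not truncated).
#' @export
predict.chu9d_fit <- function(object, newdata, ...) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, as.data.frame(newdata),
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  lp <- as.numeric(X %*% object$coefficients[colnames(X)])
  if (identical(object$estimator, "GLM")) stats::plogis(lp) else lp
}

# Evaluate code under a temporary RNG state; restores (or removes) the
# global .Random.seed afterwards so seeded fits have no side effects.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Ordinary least squares with heteroskedasticity-robust inference
#'
#' Least-squares fit with HC1 sandwich standard errors and Wald
#' (normal-approximation) p-values, the baseline estimator for mapping
#' algorithms.
#'
#' @param formula Model formula, e.g. `chu9d ~ ks_i1 + ks_i3`.
#' @param data Data frame (typically a [paired_dataset()]).
#' @return A `chu9d_fit` with coefficients, robust SEs, p-values, fitted
#'   values and `r_squared`.
#' @export
fit_ols <- function(formula, data) {
  d <- build_design(formula, data)
  X <- d$X; y <- d$y; n <- nrow(X); p <- ncol(X)
  b <- qr.coef(d$qr, y)
  fitted <- as.numeric(X %*% b)
  r <- y - fitted
  XtX_inv <- chol2inv(qr.R(d$qr))
  meat <- crossprod(X * r)              # sum r_i^2 x_i x_i'
  V <- XtX_inv %*% meat %*% XtX_inv * n / (n - p)   # HC1
  se <- sqrt(diag(V))
  names(se) <- names(b)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(r^2) / tss else NA_real_
  new_chu9d_fit(b, se, fitted, r, estimator = "OLS", se_type = "HC1",
                convergence = list(converged = TRUE, iterations = 1L,
                                   objective = sum(r^2)),
                terms = d$terms, n = n, r_squared = r2)
}

#' Fractional logit (quasi-binomial) regression for bounded utilities
#'
#' Quasi-likelihood regression with binomial variance and logit link applied
#' directly to utilities in (0, 1]: \eqn{E[y|x] = logit^{-1}(x'\beta)}. With
#' an intercept and the canonical link, the mean of the fitted values equals
#' the observed mean at convergence, which is why this estimator reproduces
#' observed mean utilities exactly at the group level. Standard errors are
#' the robust GLM sandwich.
#'
#' @inheritParams fit_ols
#' @param tol Convergence tolerance on the coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @return A `chu9d_fit`; `fitted` are on the utility (probability) scale.
#' @export
fit_fractional_logit <- function(formula, data, tol = 1e-12, max_iter = 100L) {
  d <- build_design(formula, data)
  X <- d$X; y <- d$y; n <- nrow(X); p <- ncol(X)
  if (any(y <= 0 | y > 1)) {
    stop("fractional logit needs responses in (0, 1]; offending values: ",
         paste(utils::head(signif(y[y <= 0 | y > 1], 4), 5), collapse = ", "))
  }
  mu <- (y + mean(y)) / 2
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  eta <- stats::qlogis(mu)
  b <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    b_new <- fit$coefficients
    if (any(!is.finite(b_new))) stop("fractional logit IRLS diverged")
    delta <- max(abs(b_new - b)) / max(1, max(abs(b_new)))
    b <- b_new
    eta <- as.numeric(X %*% b)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    if (delta < tol) { converged <- TRUE; break }
  }
  # robust GLM sandwich: bread = (X'WX)^-1, meat = sum (y-mu)^2 x x'
  A <- crossprod(X * sqrt(mu * (1 - mu)))
  A_inv <- solve(A)
  B <- crossprod(X * (y - mu))
  V <- A_inv %*% B %*% A_inv
  se <- sqrt(diag(V))
  names(se) <- names(b) <- colnames(X)
  new_chu9d_fit(b, se, fitted = mu, residuals = y - mu, estimator = "GLM",
                se_type = "GLM-sandwich",
                convergence = list(converged = converged, iterations = it,
                                   objective = sum((y - mu)^2 / (mu * (1 - mu)))),
                terms = d$terms, n = n)
}
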