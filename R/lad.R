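# Least absolute deviations (median regression) and Powell's censored LAD.
#
# LAD is solved exactly by descent through basic solutions of the underlying
# linear program: an optimal LAD fit interpolates p observations (a vertex),
# adjacent vertices differ by exchanging one interpolated observation, and
# the exact minimiser along any edge direction is a weighted median of
# residual/direction ratios. Descending until no edge improves therefore
# terminates at the global optimum (the objective is convex piecewise
# linear). This matches the simplex solution of the LP formulation with
# split positive/negative residuals, without forming the LP tableau.

# Lower weighted median of values `v` with positive weights `w`: the
# smallest v at which the cumulative weight reaches half the total. Returns
# the value and its (original) index.
weighted_median <- function(v, w) {
  o <- order(v)
  cw <- cumsum(w[o])
  i <- which(cw >= sum(w) / 2)[1L]
  list(value = v[o[i]], index = o[i])
}

# Greedy full-rank basis: walk rows in the given preference order, keep a
# row if it is linearly independent of those kept so far, stop at p rows.
initial_basis <- function(X, pref_order) {
  p <- ncol(X)
  basis <- integer(0)
  M <- matrix(0, 0, p)
  for (i in pref_order) {
    cand <- rbind(M, X[i, ])
    if (qr(cand)$rank > nrow(M)) {
      M <- cand
      basis <- c(basis, i)
      if (length(basis) == p) break
    }
  }
  if (length(basis) < p) stop("could not find a full-rank basis")
  basis
}

lad_solve <- function(X, y, max_iter = NULL, warm = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (n < p) stop("LAD needs at least p observations")
  if (qr(X)$rank < p) stop("LAD design is rank deficient")
  if (n == p) {
    b <- solve(X, y)
    return(list(coefficients = as.numeric(b), objective = 0,
                iterations = 0L, converged = TRUE, basis = seq_len(n)))
  }
  if (is.null(max_iter)) max_iter <- max(200L, 10L * n)
  b0 <- if (is.null(warm)) qr.coef(qr(X), y) else warm
  r0 <- y - as.numeric(X %*% b0)
  basis <- initial_basis(X, order(abs(r0)))
  b <- solve(X[basis, , drop = FALSE], y[basis])
  r <- y - as.numeric(X %*% b)
  f <- sum(abs(r))
  gtol <- 1e-12 * max(1, max(abs(X)))
  ftol <- 1e-11 * (1 + f)
  converged <- FALSE
  it <- 0L
  tie_moves <- 0L
  while (it < max_iter) {
    it <- it + 1L
    D <- solve(X[basis, , drop = FALSE])        # edge directions (columns)
    G <- X %*% D                                # n x p slopes along each edge
    best <- list(gain = 0)
    tie <- NULL
    for (l in seq_len(p)) {
      g <- G[, l]
      cand <- which(abs(g) > gtol)
      wm <- weighted_median(r[cand] / g[cand], abs(g[cand]))
      f_l <- sum(abs(r - wm$value * g))
      gain <- f - f_l
      if (gain > best$gain) {
        best <- list(gain = gain, l = l, t = wm$value, enter = cand[wm$index],
                     f = f_l)
      } else if (is.null(tie) && gain >= -ftol && abs(wm$value) > gtol) {
        # equal-objective vertex reachable: the line's lower weighted median
        # differs from the current point (tie case, e.g. even-n medians)
        tie <- list(l = l, t = wm$value, enter = cand[wm$index], f = f_l)
      }
    }
    if (best$gain > ftol) {
      tie_moves <- 0L
    } else if (!is.null(tie) && tie_moves < 2L * p) {
      # drift to the lower-median vertex among objective ties
      tie_moves <- tie_moves + 1L
      best <- c(tie, gain = 0)
    } else {
      converged <- TRUE
      break
    }
    b <- b + best$t * D[, best$l]
    basis[best$l] <- best$enter
    r <- y - as.numeric(X %*% b)
    f <- sum(abs(r))
  }
  list(coefficients = as.numeric(b), objective = f, iterations = it,
       converged = converged, basis = sort(basis))
}

boot_se <- function(X, y, point_fn, B, seed) {
  p <- ncol(X)
  n <- nrow(X)
  est <- matrix(NA_real_, B, p)
  failures <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      cb <- tryCatch(point_fn(X[idx, , drop = FALSE], y[idx]),
                     error = function(e) NULL)
      if (is.null(cb)) failures <- failures + 1L else est[b, ] <- cb
    }
  })
  list(se = apply(est, 2, stats::sd, na.rm = TRUE), failures = failures)
}

#' Least absolute deviations (median) regression
#'
#' Minimises the sum of absolute residuals exactly, via descent over basic
#' solutions of the LAD linear program (see Details). For an intercept-only
#' model this returns the lower sample median. Standard errors, when
#' requested, come from a seeded nonparametric bootstrap of respondent
#' records.
#'
#' @inheritParams fit_ols
#' @param se `"bootstrap"` for pairs-bootstrap SEs, `"none"` for `NA` SEs
#'   (fast, point estimate only).
#' @param B Bootstrap replications.
#' @param seed Seed for the bootstrap resampling.
#' @return A `chu9d_fit`; `convergence$objective` is the minimised sum of
#'   absolute residuals.
#' @export
fit_lad <- function(formula, data, se = c("bootstrap", "none"), B = 100L,
                    seed = 1L) {
  se <- match.arg(se)
  d <- build_design(formula, data, allow_exact = TRUE)
  sol <- lad_solve(d$X, d$y)
  b <- stats::setNames(sol$coefficients, colnames(d$X))
  fitted <- as.numeric(d$X %*% sol$coefficients)
  ses <- rep(NA_real_, length(b))
  if (se == "bootstrap") {
    bs <- boot_se(d$X, d$y, function(X, y) lad_solve(X, y)$coefficients,
                  B = B, seed = seed)
    ses <- bs$se
  }
  names(ses) <- names(b)
  new_chu9d_fit(b, ses, fitted, d$y - fitted, estimator = "LAD",
                se_type = if (se == "bootstrap") sprintf("bootstrap(B=%d)", B) else "none",
                convergence = list(converged = sol$converged,
                                   iterations = sol$iterations,
                                   objective = sol$objective),
                terms = d$terms, n = nrow(d$X))
}

clad_solve <- function(X, y, censor, max_iter = 100L) {
  n <- nrow(X)
  retained <- seq_len(n)
  ctol <- 1e-10
  b <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sol <- lad_solve(X[retained, , drop = FALSE], y[retained], warm = b)
    b <- sol$coefficients
    fitted_all <- as.numeric(X %*% b)
    new_ret <- which(fitted_all <= censor + ctol)   # ties at the boundary retained
    if (!length(new_ret)) stop("no observations retained: all fitted values at or above the censor point")
    if (length(new_ret) == length(retained) && all(new_ret == retained)) {
      converged <- TRUE
      break
    }
    retained <- new_ret
  }
  list(coefficients = b, retained = retained, iterations = it,
       converged = converged,
       objective = sum(abs(y - pmin(as.numeric(X %*% b), censor))))
}

#' Censored least absolute deviations (Powell) regression
#'
#' Median regression consistent under fixed (upper) censoring of the
#' response, for example utilities observed only up to the full-health
#' ceiling of 1. Estimated by the iterative trimming algorithm: fit LAD on
#' the current subsample, retain the observations whose fitted values lie
#' below the censor point (ties at the boundary are retained), and repeat
#' until the retained set is stable. When no fitted value ever reaches the
#' censor point the estimate coincides with plain LAD.
#'
#' @inheritParams fit_lad
#' @param upper_censor Censoring point (default 1, the utility ceiling).
#' @param max_iter Maximum trimming iterations; non-convergence is flagged,
#'   not an error.
#' @return A `chu9d_fit`; `fitted` are the latent (uncensored) fitted
#'   values, `retained` the indices of the final retained subsample.
#' @export
fit_clad <- function(formula, data, upper_censor = 1,
                     se = c("bootstrap", "none"), B = 200L, seed = 1L,
                     max_iter = 100L) {
  se <- match.arg(se)
  d <- build_design(formula, data)
  if (!any(d$y < upper_censor)) {
    stop("CLAD needs some responses strictly below the censor point")
  }
  sol <- clad_solve(d$X, d$y, upper_censor, max_iter = max_iter)
  b <- stats::setNames(sol$coefficients, colnames(d$X))
  fitted <- as.numeric(d$X %*% sol$coefficients)
  ses <- rep(NA_real_, length(b))
  if (se == "bootstrap") {
    bs <- boot_se(d$X, d$y,
                  function(X, y) clad_solve(X, y, upper_censor,
                                            max_iter = max_iter)$coefficients,
                  B = B, seed = seed)
    ses <- bs$se
  }
  names(ses) <- names(b)
  new_chu9d_fit(b, ses, fitted, d$y - fitted, estimator = "CLAD",
                se_type = if (se == "bootstrap") sprintf("bootstrap(B=%d)", B) else "none",
                convergence = list(converged = sol$converged,
                                   iterations = sol$iterations,
                                   objective = sol$objective),
                terms = d$terms, n = nrow(d$X), retained = sol$retained)
}
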