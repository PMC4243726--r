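# Goodness of fit (MAE/RMSE with the truncate-at-one adjustment) and the two
# internal validation schemes: 5-fold cross-validation with pooled held-out
# errors, and random-subsample validation of a full-sample algorithm.

#' Goodness of fit of utility predictions
#'
#' Mean absolute error, root mean squared error and the mean/min/max of the
#' predictions, both raw and after truncating predictions above 1 to 1. The
#' truncation adjustment never worsens the pointwise error when all observed
#' utilities are at most 1, so truncated MAE/RMSE are never larger than the
#' raw ones on admissible data.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Object of class `chu9d_gof`: list with `mae`, `rmse`,
#'   `mean_pred`, `min_pred`, `max_pred`, the same five with suffix
#'   `_trunc`, and `n`.
#' @export
gof <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length")
  }
  if (!length(observed)) stop("empty input")
  if (anyNA(observed) || anyNA(predicted)) stop("missing values")
  tr <- pmin(predicted, 1)
  e <- predicted - observed
  et <- tr - observed
  structure(list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)),
                 mean_pred = mean(predicted), min_pred = min(predicted),
                 max_pred = max(predicted),
                 mae_trunc = mean(abs(et)), rmse_trunc = sqrt(mean(et^2)),
                 mean_pred_trunc = mean(tr), min_pred_trunc = min(tr),
                 max_pred_trunc = max(tr), n = length(observed)),
            class = "chu9d_gof")
}

#' @export
print.chu9d_gof <- function(x, ...) {
  cat(sprintf("n = %d\n", x$n))
  cat(sprintf("raw:       MAE %.4f  RMSE %.4f  mean %.4f  min %.4f  max %.4f\n",
              x$mae, x$rmse, x$mean_pred, x$min_pred, x$max_pred))
  cat(sprintf("truncated: MAE %.4f  RMSE %.4f  mean %.4f  min %.4f  max %.4f\n",
              x$mae_trunc, x$rmse_trunc, x$mean_pred_trunc, x$min_pred_trunc,
              x$max_pred_trunc))
  invisible(x)
}

#' Random fold assignment for k-fold cross-validation
#'
#' Seeded uniform shuffle followed by a block split: the k groups partition
#' the records and their sizes differ by at most one. Reproducible from the
#' seed.
#'
#' @param n Number of records.
#' @param k Number of folds (default 5).
#' @param seed Seed for the shuffle.
#' @return Integer vector of length `n` with fold labels in `1..k`.
#' @export
fold_plan <- function(n, k = 5L, seed) {
  stopifnot(n >= k, k >= 2)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

recipe_formula <- function(model, estimator, selected = NULL) {
  if (model == "model1") {
    # published specification: index + squared index, except the fractional
    # logit, whose link already captures the curvature (squared term dropped)
    if (tolower(estimator) == "glm") chu9d ~ ks_index
    else chu9d ~ ks_index + I(ks_index^2)
  } else {
    if (is.null(selected) || !length(selected)) chu9d ~ 1
    else stats::reformulate(selected, response = "chu9d")
  }
}

#' 5-fold cross-validation of a mapping recipe
#'
#' The full sample is split into `k` random groups ([fold_plan()]); for each
#' group the mapping model is re-estimated on the other groups (80% of the
#' sample at k = 5) — including, for the item-score model, re-running the
#' stepwise selection — and utilities are predicted for the held-out group.
#' The held-out errors are pooled over all folds (each record predicted
#' exactly once) and summarised with [gof()].
#'
#' @param data A [paired_dataset()] (or data frame) with `chu9d` and the
#'   model's predictors.
#' @param model `"model1"` (index + index squared) or `"model2"` (item
#'   scores).
#' @param estimator `"ols"`, `"clad"`, `"mm"` or `"glm"`.
#' @param seed Seed for the fold assignment.
#' @param k Number of folds.
#' @param stepwise Re-run forward stepwise selection on each estimation
#'   sample (`model2` only).
#' @param p_enter Stepwise entry threshold.
#' @param candidates Candidate items for stepwise selection.
#' @param ... Passed to the estimator.
#' @return List of class `chu9d_cv`: `gof` (pooled), `fold` (assignment),
#'   `predictions` (data frame with observed, raw and truncated predictions
#'   and fold id) and `selected` (per-fold term sets).
#' @export
crossvalidate_5fold <- function(data, model = c("model2", "model1"),
                                estimator = "mm", seed, k = 5L,
                                stepwise = TRUE, p_enter = 0.05,
                                candidates = names(ks_items()), ...) {
  model <- match.arg(model)
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 2 * k) stop("too few records for ", k, "-fold cross-validation")
  fold <- fold_plan(n, k = k, seed = seed)
  raw <- numeric(n)
  selected <- vector("list", k)
  fitter <- estimator_fitter(estimator)
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    if (model == "model2" && stepwise) {
      sw <- forward_stepwise(train, response = "chu9d",
                             candidates = candidates, estimator = estimator,
                             p_enter = p_enter, ...)
      selected[[f]] <- sw$selected
    } else if (model == "model2") {
      selected[[f]] <- candidates
    }
    fml <- recipe_formula(model, estimator, selected[[f]])
    fit <- fitter(fml, train, ...)
    raw[fold == f] <- predict(fit, test)
  }
  g <- gof(data$chu9d, raw)
  preds <- data.frame(fold = fold, observed = data$chu9d, raw = raw,
                      truncated = pmin(raw, 1))
  structure(list(gof = g, fold = fold, predictions = preds,
                 selected = selected, model = model, estimator = estimator,
                 seed = seed, k = k),
            class = "chu9d_cv")
}

#' @export
print.chu9d_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s, %s), pooled held-out errors:\n",
              x$k, x$estimator, x$model))
  print(x$gof)
  invisible(x)
}

#' Random-subsample validation of a full-sample algorithm
#'
#' Applies a fixed mapping specification (typically estimated on the full
#' sample) to random subsamples drawn without replacement, and reports
#' goodness of fit per subsample size — a stability check of the algorithm's
#' group-level accuracy.
#'
#' @param data A [paired_dataset()] with observed `chu9d`.
#' @param spec A `chu9d_spec` to evaluate.
#' @param sizes Subsample sizes (each at most `nrow(data)`).
#' @param seed Seed for the subsampling.
#' @return Named list of [gof()] results, one per size.
#' @export
subsample_validation <- function(data, spec, sizes = c(100L, 300L, 500L),
                                 seed) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (any(sizes > n)) stop("subsample size exceeds the sample size ", n)
  if (any(sizes < 1)) stop("subsample sizes must be positive")
  out <- vector("list", length(sizes))
  names(out) <- paste0("n", sizes)
  with_seed(seed, {
    for (i in seq_along(sizes)) {
      idx <- sample.int(n, sizes[i])
      sub <- data[idx, , drop = FALSE]
      pr <- predict_chu9d(sub, spec, truncate = FALSE)
      out[[i]] <- gof(sub$chu9d, pr$raw)
    }
  })
  out
}
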