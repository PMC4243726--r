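# Model selection machinery: forward stepwise entry on robust Wald
# p-values, bootstrap selection frequencies, and variance inflation factors.

estimator_fitter <- function(estimator) {
  switch(tolower(estimator),
         ols = fit_ols,
         lad = fit_lad,
         clad = fit_clad,
         mm = fit_mm,
         glm = fit_fractional_logit,
         stop("unknown estimator '", estimator,
              "'; use one of ols, clad, mm, glm, lad"))
}

#' Forward stepwise selection on robust p-values
#'
#' Greedy forward entry: at each step every remaining candidate is added in
#' turn to the current model, the candidate with the smallest robust Wald
#' p-value enters if that p-value is below `p_enter`, and selection stops
#' otherwise. Ties are broken in favour of the earlier candidate in
#' `candidates`. Selection is run independently per estimator, since
#' different estimators can retain different item subsets.
#'
#' @param data Data frame with the response and candidate columns.
#' @param response Response column name (default `"chu9d"`).
#' @param candidates Character vector of candidate term names, in tie-break
#'   order (default the ten items).
#' @param estimator `"ols"`, `"clad"`, `"mm"` or `"glm"`.
#' @param p_enter Entry threshold on the candidate's p-value.
#' @param always Terms forced into every model (never tested).
#' @param ... Passed to the estimator (e.g. `se`, `B`, `seed`, `n_subsets`).
#' @return List with `selected` (character), `trace` (data frame of entered
#'   term and entry p-value per step), and `fit` (the final `chu9d_fit`, or
#'   `NULL` if nothing was selected and `always` is empty).
#' @export
forward_stepwise <- function(data, response = "chu9d",
                             candidates = names(ks_items()),
                             estimator = "ols", p_enter = 0.05,
                             always = character(), ...) {
  stopifnot(length(candidates) >= 1)
  fitter <- estimator_fitter(estimator)
  data <- as.data.frame(data)
  current <- always
  remaining <- setdiff(candidates, always)
  trace <- data.frame(step = integer(), term = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  selected <- character()
  step <- 0L
  final_fit <- NULL
  while (length(remaining)) {
    pvals <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      fml <- stats::reformulate(c(current, remaining[i]), response = response)
      fit <- tryCatch(fitter(fml, data, ...), error = function(e) e)
      if (inherits(fit, "error")) {
        if (grepl("rank deficient", conditionMessage(fit))) {
          next  # candidate collinear with the current model: cannot enter
        }
        stop("estimator failed while testing '", remaining[i], "': ",
             conditionMessage(fit),
             "\npartial selection: ", paste(selected, collapse = ", "))
      }
      fits[[i]] <- fit
      pvals[i] <- fit$p_values[[remaining[i]]]
    }
    best <- which.min(pvals)    # first minimum wins exact ties
    if (!length(best) || !(pvals[best] < p_enter)) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, term = remaining[best],
                                     p_value = pvals[best],
                                     stringsAsFactors = FALSE))
    selected <- c(selected, remaining[best])
    current <- c(current, remaining[best])
    final_fit <- fits[[best]]
    remaining <- remaining[-best]
  }
  list(selected = selected, trace = trace, fit = final_fit)
}

#' Bootstrap stepwise selection frequencies
#'
#' Resamples respondent records (pairs) with replacement `B` times, runs
#' [forward_stepwise()] on each resample, and counts how often each
#' candidate is selected — a stability ranking of the candidate items.
#'
#' @inheritParams forward_stepwise
#' @param B Bootstrap replications (default 100).
#' @param seed Seed for the resampling.
#' @return List with `counts` (named integer vector, per candidate),
#'   `frequencies` (`counts / B_effective`), `B`, and `failures` (resamples
#'   where the estimator failed; recorded, not fatal).
#' @export
bootstrap_stepwise <- function(data, response = "chu9d",
                               candidates = names(ks_items()),
                               estimator = "ols", p_enter = 0.05,
                               B = 100L, seed = 1L, ...) {
  stopifnot(B >= 1)
  data <- as.data.frame(data)
  n <- nrow(data)
  counts <- stats::setNames(integer(length(candidates)), candidates)
  failures <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(
        forward_stepwise(data[idx, , drop = FALSE], response = response,
                         candidates = candidates, estimator = estimator,
                         p_enter = p_enter, ...),
        error = function(e) NULL)
      if (is.null(res)) failures <- failures + 1L
      else counts[res$selected] <- counts[res$selected] + 1L
    }
  })
  eff <- B - failures
  list(counts = counts,
       frequencies = if (eff > 0) counts / eff else counts * NA_real_,
       B = B, failures = failures)
}

#' Variance inflation factors
#'
#' VIF of each term: `1 / (1 - R^2_j)` from the least-squares regression of
#' term `j` on the other terms (with intercept). Perfect collinearity is
#' reported as an infinite VIF rather than an error.
#'
#' @param data Data frame holding the terms.
#' @param terms Character vector of at least two column names.
#' @return List with `vif` (named vector), `mean_vif` and `max_vif`.
#' @export
vif <- function(data, terms = names(ks_items())) {
  data <- as.data.frame(data)
  stopifnot(length(terms) >= 2, all(terms %in% names(data)))
  X <- as.matrix(data[, terms, drop = FALSE])
  if (anyNA(X)) stop("missing values among VIF terms")
  out <- stats::setNames(numeric(length(terms)), terms)
  for (j in seq_along(terms)) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    rss <- sum(stats::lm.fit(Zj, yj)$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss <= 0) { out[j] <- Inf; next }
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  list(vif = out, mean_vif = mean(out), max_vif = max(out))
}
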