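#' Construct a CHU9D mapping algorithm specification
#'
#' A mapping specification is a complete, self-contained description of one
#' crosswalk from KIDSCREEN-10 responses to CHU9D utilities: either the
#' index-quadratic form
#' \deqn{CHU9D = \alpha + \beta_1 KS + \beta_2 KS^2}
#' (`form = "index_quadratic"`) on the KIDSCREEN-10 index, or the additive
#' item-score form
#' \deqn{CHU9D = \alpha + \sum_j \gamma_j KS\_Ij}
#' (`form = "item_linear"`) on a selected subset of raw item scores. With
#' `link = "logit"` the right-hand side is a linear predictor and the
#' prediction is its inverse logit (fractional logit algorithms); with the
#' identity link the prediction is the linear predictor itself.
#'
#' @param form `"index_quadratic"` or `"item_linear"`.
#' @param intercept Intercept \eqn{\alpha}.
#' @param beta1,beta2 Index and squared-index coefficients
#'   (`index_quadratic` only; `beta2 = NULL` omits the quadratic term).
#' @param gammas Named numeric vector of item coefficients keyed by
#'   `ks_i1` .. `ks_i10` (`item_linear` only, 1-10 entries).
#' @param link `"identity"` or `"logit"`. The logit link is only admissible
#'   for fractional-logit (`estimator = "GLM"`) algorithms.
#' @param estimator Label of the estimator that produced the coefficients:
#'   `"OLS"`, `"CLAD"`, `"MM"` or `"GLM"`.
#' @param value_set CHU9D tariff the utilities refer to:
#'   `"AU_adolescent_BWS"` or `"UK_adult_SG"`.
#' @param truncate_upper_at_1 Should predictions above 1 be truncated to 1
#'   by default when the spec is applied?
#' @param name Optional identifier.
#' @param se Optional named numeric vector of robust standard errors.
#' @param source,provenance Optional free-text provenance notes.
#' @return Object of class `chu9d_spec`.
#' @export
mapping_spec <- function(form = c("index_quadratic", "item_linear"),
                         intercept, beta1 = NULL, beta2 = NULL, gammas = NULL,
                         link = c("identity", "logit"),
                         estimator = c("OLS", "CLAD", "MM", "GLM"),
                         value_set = c("AU_adolescent_BWS", "UK_adult_SG"),
                         truncate_upper_at_1 = TRUE, name = NULL, se = NULL,
                         source = NULL, provenance = NULL) {
  form <- match.arg(form)
  link <- match.arg(link)
  estimator <- match.arg(estimator)
  value_set <- match.arg(value_set)
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    stop("`intercept` must be a finite scalar")
  }
  if (link == "logit" && estimator != "GLM") {
    stop("the logit link is only admissible for GLM (fractional logit) algorithms")
  }
  if (form == "index_quadratic") {
    if (is.null(beta1) || !is.finite(beta1)) stop("`beta1` is required for the index form")
    if (!is.null(gammas)) stop("`gammas` are not part of the index form")
    if (!is.null(beta2) && !is.finite(beta2)) stop("`beta2` must be finite or NULL")
  } else {
    if (is.null(gammas) || length(gammas) < 1L || length(gammas) > 10L) {
      stop("the item form needs 1-10 `gammas`")
    }
    bad <- setdiff(names(gammas), names(ks_items()))
    if (is.null(names(gammas)) || length(bad)) {
      stop("`gammas` must be named by valid item labels; offending: ",
           paste(bad, collapse = ", "))
    }
    if (!all(is.finite(gammas))) stop("`gammas` must be finite")
    if (!is.null(beta1) || !is.null(beta2)) {
      stop("`beta1`/`beta2` are not part of the item form")
    }
  }
  structure(list(name = name, form = form, link = link, estimator = estimator,
                 value_set = value_set, intercept = as.numeric(intercept),
                 beta1 = if (!is.null(beta1)) as.numeric(beta1),
                 beta2 = if (!is.null(beta2)) as.numeric(beta2),
                 gammas = if (!is.null(gammas)) stats::setNames(as.numeric(gammas), names(gammas)),
                 se = se, source = source, provenance = provenance,
                 truncate_upper_at_1 = isTRUE(truncate_upper_at_1)),
            class = "chu9d_spec")
}

#' @export
print.chu9d_spec <- function(x, ...) {
  cat("CHU9D mapping algorithm", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  form:", x$form, "| link:", x$link, "| estimator:", x$estimator,
      "| value set:", x$value_set, "\n")
  cat("  intercept:", format(x$intercept), "\n")
  if (x$form == "index_quadratic") {
    cat("  beta1 (KS):", format(x$beta1),
        if (!is.null(x$beta2)) paste("| beta2 (KS^2):", format(x$beta2)) else "| no quadratic term", "\n")
  } else {
    cat("  item coefficients:\n")
    print(x$gammas)
  }
  cat("  truncate predictions above 1:", x$truncate_upper_at_1, "\n")
  invisible(x)
}

registry_path <- function() {
  system.file("extdata", "chu9d_algorithms.json", package = "chu9dmap",
              mustWork = TRUE)
}

registry_entries <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- jsonlite::read_json(registry_path())$algorithms
    }
    cache
  }
})

spec_from_entry <- function(e) {
  gammas <- NULL
  if (!is.null(e$gammas)) {
    gammas <- vapply(e$gammas, function(s) as.numeric(s), numeric(1))
  }
  se <- vapply(e$se, function(s) as.numeric(s), numeric(1))
  mapping_spec(form = e$form,
               intercept = as.numeric(e$intercept),
               beta1 = if (!is.null(e$beta1)) as.numeric(e$beta1),
               beta2 = if (!is.null(e$beta2)) as.numeric(e$beta2),
               gammas = gammas,
               link = e$link, estimator = e$estimator,
               value_set = e$value_set,
               truncate_upper_at_1 = isTRUE(e$truncate_upper_at_1),
               name = e$name, se = se,
               source = "packaged registry",
               provenance = e$provenance)
}

#' List the packaged mapping algorithms
#'
#' Sixteen published coefficient sets are packaged: {AU adolescent, UK adult}
#' value sets x {OLS, CLAD, MM, GLM} estimators x {model1 = index quadratic,
#' model2 = stepwise item scores}.
#'
#' @return Character vector of algorithm identifiers, e.g. `"AU/MM/model2"`.
#' @export
chu9d_algorithms <- function() {
  vapply(registry_entries(), function(e) e$name, character(1))
}

#' Load a packaged mapping algorithm
#'
#' @param name Identifier of the form `"<value set>/<estimator>/<model>"`,
#'   e.g. `"AU/MM/model2"` (the preferred published algorithm). See
#'   [chu9d_algorithms()] for the full list.
#' @return A [mapping_spec()] object with the published coefficients.
#' @export
#' @examples
#' chu9d_algorithm("AU/MM/model2")
chu9d_algorithm <- function(name) {
  entries <- registry_entries()
  nm <- vapply(entries, function(e) e$name, character(1))
  i <- match(name, nm)
  if (is.na(i)) {
    stop("unknown algorithm '", name, "'. Available: ",
         paste(nm, collapse = ", "))
  }
  spec_from_entry(entries[[i]])
}

#' Serialise / read a mapping specification as JSON
#'
#' Round-trip stable: reading a written spec reproduces the coefficients
#' exactly (coefficients are serialised as decimal strings at full
#' precision).
#'
#' @param spec A `chu9d_spec`.
#' @param path Output / input file path.
#' @return `write_mapping_spec` returns `path` invisibly;
#'   `read_mapping_spec` returns a `chu9d_spec`.
#' @export
write_mapping_spec <- function(spec, path) {
  stopifnot(inherits(spec, "chu9d_spec"))
  num <- function(x) if (is.null(x)) NULL else format(x, digits = 17, scientific = FALSE, trim = TRUE)
  obj <- list(name = spec$name, form = spec$form, link = spec$link,
              estimator = spec$estimator, value_set = spec$value_set,
              intercept = num(spec$intercept),
              beta1 = num(spec$beta1), beta2 = num(spec$beta2),
              gammas = if (!is.null(spec$gammas)) as.list(stats::setNames(num(spec$gammas), names(spec$gammas))),
              se = if (!is.null(spec$se)) as.list(stats::setNames(num(spec$se), names(spec$se))),
              source = spec$source, provenance = spec$provenance,
              truncate_upper_at_1 = spec$truncate_upper_at_1)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mapping_spec
#' @export
read_mapping_spec <- function(path) {
  e <- jsonlite::read_json(path)
  spec_from_entry(e)
}

#' Convert a fitted model into a mapping specification
#'
#' Turns a `chu9d_fit` whose predictors are either the index (plus optional
#' squared index) or a subset of item scores into a self-contained
#' [mapping_spec()] that can be serialised, registered and applied to new
#' data.
#'
#' @param fit A `chu9d_fit` from [fit_ols()], [fit_clad()], [fit_mm()] or
#'   [fit_fractional_logit()].
#' @param value_set `"AU"`/`"UK"` shorthand or a full value-set label.
#' @param name Optional identifier for the spec.
#' @param truncate_upper_at_1 Truncation default recorded on the spec.
#' @return A `chu9d_spec`.
#' @export
as_mapping_spec <- function(fit, value_set = "AU_adolescent_BWS", name = NULL,
                            truncate_upper_at_1 = TRUE) {
  stopifnot(inherits(fit, "chu9d_fit"))
  value_set <- switch(value_set, AU = "AU_adolescent_BWS",
                      UK = "UK_adult_SG", value_set)
  cf <- fit$coefficients
  if (!"(Intercept)" %in% names(cf)) stop("fit has no intercept")
  est_label <- switch(fit$estimator, LAD = "CLAD", fit$estimator)
  others <- setdiff(names(cf), "(Intercept)")
  items <- names(ks_items())
  if (all(others %in% items)) {
    mapping_spec(form = "item_linear", intercept = cf[["(Intercept)"]],
                 gammas = cf[others],
                 link = if (fit$estimator == "GLM") "logit" else "identity",
                 estimator = est_label, value_set = value_set,
                 truncate_upper_at_1 = truncate_upper_at_1, name = name,
                 se = fit$se, source = "fitted")
  } else if (all(others %in% c("ks_index", "I(ks_index^2)", "ks_index_sq"))) {
    sq <- intersect(c("I(ks_index^2)", "ks_index_sq"), others)
    mapping_spec(form = "index_quadratic", intercept = cf[["(Intercept)"]],
                 beta1 = cf[["ks_index"]],
                 beta2 = if (length(sq)) cf[[sq[1]]],
                 link = if (fit$estimator == "GLM") "logit" else "identity",
                 estimator = est_label, value_set = value_set,
                 truncate_upper_at_1 = truncate_upper_at_1, name = name,
                 se = fit$se, source = "fitted")
  } else {
    stop("fit predictors are neither an item subset nor the index form: ",
         paste(others, collapse = ", "))
  }
}

spec_linear_predictor <- function(newdata, spec) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  newdata <- as.data.frame(newdata)
  if (!nrow(newdata)) stop("no records to predict from")
  if (spec$form == "index_quadratic") {
    if (!("ks_index" %in% names(newdata))) {
      stop("this algorithm needs a `ks_index` column (KIDSCREEN-10 index); ",
           "item scores alone are not sufficient for the index form")
    }
    ks <- newdata$ks_index
    if (anyNA(ks)) stop("missing ks_index values")
    lp <- spec$intercept + spec$beta1 * ks +
      if (!is.null(spec$beta2)) spec$beta2 * ks^2 else 0
  } else {
    need <- names(spec$gammas)
    miss <- setdiff(need, names(newdata))
    if (length(miss)) {
      stop("record(s) lack item(s) named by the algorithm: ",
           paste(miss, collapse = ", "))
    }
    X <- as.matrix(newdata[, need, drop = FALSE])
    if (anyNA(X)) stop("missing item values")
    lp <- spec$intercept + as.numeric(X %*% spec$gammas)
  }
  lp
}

#' Predict CHU9D utilities from a mapping algorithm
#'
#' Applies a mapping specification to respondent records, returning raw and
#' truncated predictions. Predictions from identity-link algorithms can
#' exceed 1 (or fall below the value-set floor); the standard adjustment
#' truncates predictions above 1 to 1, which never worsens the pointwise
#' error when observed utilities are at most 1. Individual-level predictions
#' carry substantial error; group-level (mean) use is recommended.
#'
#' @param newdata Data frame of records (or a single named vector). The
#'   index form needs a `ks_index` column; the item form needs the item
#'   columns named by the algorithm.
#' @param spec A `chu9d_spec` (see [mapping_spec()], [chu9d_algorithm()]).
#' @param truncate Apply upper truncation at 1? Defaults to the spec's
#'   `truncate_upper_at_1` flag.
#' @param lower_truncate Optional lower truncation bound (e.g. the AU tariff
#'   floor 0.33); `NULL` (default) leaves the lower tail untouched, as in
#'   the published algorithms.
#' @return Object of class `chu9d_predictions`: a data frame with columns
#'   `raw` and `truncated`, one row per record.
#' @export
#' @examples
#' rec <- stats::setNames(rep(5, 10), names(ks_items()))
#' predict_chu9d(rec, chu9d_algorithm("AU/MM/model2"))
predict_chu9d <- function(newdata, spec, truncate = spec$truncate_upper_at_1,
                          lower_truncate = NULL) {
  stopifnot(inherits(spec, "chu9d_spec"))
  lp <- spec_linear_predictor(newdata, spec)
  raw <- if (spec$link == "logit") stats::plogis(lp) else lp
  trunc <- if (isTRUE(truncate)) pmin(raw, 1) else raw
  if (!is.null(lower_truncate)) trunc <- pmax(trunc, lower_truncate)
  structure(data.frame(raw = raw, truncated = trunc),
            class = c("chu9d_predictions", "data.frame"),
            spec_name = spec$name)
}

#' Summarise a batch of CHU9D predictions
#'
#' Mean, minimum and maximum of the raw and truncated predictions, the
#' group-level quantities reported for mapping algorithms.
#'
#' @param object A `chu9d_predictions` object.
#' @param ... Unused.
#' @return Data frame with rows `raw` and `truncated` and columns
#'   `mean`, `min`, `max`, `n`.
#' @export
summary.chu9d_predictions <- function(object, ...) {
  s <- function(x) c(mean = mean(x), min = min(x), max = max(x), n = length(x))
  out <- as.data.frame(rbind(raw = s(object$raw), truncated = s(object$truncated)))
  out
}
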