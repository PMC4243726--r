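#' @keywords internal
"_PACKAGE"

#' KIDSCREEN-10 item labels
#'
#' Canonical column names and short descriptions of the ten KIDSCREEN-10
#' items. All package functions use the column names `ks_i1` .. `ks_i10`,
#' coded 1-5 with higher levels indicating better health-related quality of
#' life on every item.
#'
#' @return Named character vector of length 10: names are the canonical
#'   column names, values are the item descriptions.
#' @export
#' @examples
#' ks_items()
ks_items <- function() {
  c(ks_i1  = "felt fit and well",
    ks_i2  = "felt full of energy",
    ks_i3  = "felt sad",
    ks_i4  = "felt lonely",
    ks_i5  = "had enough time for yourself",
    ks_i6  = "able to do the things you want in free time",
    ks_i7  = "parent(s) treated you fairly",
    ks_i8  = "had fun with friends",
    ks_i9  = "got on well at school",
    ks_i10 = "been able to pay attention")
}

#' Validate one respondent's KIDSCREEN-10 item responses
#'
#' Checks that a record carries all ten items as integer levels in 1-5 and
#' optionally reverse-codes declared negatively worded items (level ->
#' 6 - level) so that higher always means better HRQoL. Records with missing
#' values are rejected (the package is complete-case throughout).
#'
#' @param record Named list, one-row data frame, or named numeric vector
#'   containing `ks_i1` .. `ks_i10`.
#' @param reverse_coded Character vector of item names (subset of
#'   `names(ks_items())`) whose raw coding runs in the unhealthy direction
#'   and must be flipped at ingest.
#' @return Named integer vector of length 10 (uniform coding, higher =
#'   better).
#' @export
#' @examples
#' validate_responses(as.list(stats::setNames(rep(3, 10), names(ks_items()))))
validate_responses <- function(record, reverse_coded = character()) {
  items <- names(ks_items())
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) stop("`record` must be a single row")
    record <- as.list(record)
  }
  record <- as.list(record)
  missing_cols <- setdiff(items, names(record))
  if (length(missing_cols)) {
    stop("record lacks item field(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_rc <- setdiff(reverse_coded, items)
  if (length(bad_rc)) {
    stop("unknown item(s) in `reverse_coded`: ", paste(bad_rc, collapse = ", "))
  }
  out <- integer(10)
  names(out) <- items
  for (it in items) {
    v <- record[[it]]
    if (length(v) != 1L || is.na(v)) {
      stop("missing value on ", toupper(sub("ks_i", "KS_I", it)),
           ": records must be complete-case")
    }
    if (!is.numeric(v) || v != as.integer(v) || v < 1 || v > 5) {
      stop("invalid level for ", toupper(sub("ks_i", "KS_I", it)),
           ": got ", v, ", expected an integer in 1..5")
    }
    out[[it]] <- as.integer(v)
  }
  if (length(reverse_coded)) out[reverse_coded] <- 6L - out[reverse_coded]
  out
}

#' Raw KIDSCREEN-10 sum score
#'
#' Equal-weight sum of the ten item levels, the first step of the
#' KIDSCREEN-10 index construction. Bounded in \[10, 50\].
#'
#' @param items Validated item vector (see [validate_responses()]).
#' @return Integer sum in 10..50.
#' @export
raw_sum <- function(items) {
  items <- validate_responses(as.list(items))
  sum(items)
}

#' Rasch lookup table for the KIDSCREEN-10 index
#'
#' The KIDSCREEN-10 index is built in three steps: raw sum over the ten
#' items, conversion of each attainable sum (10..50) to a Rasch person
#' parameter via a lookup table, and an affine transformation of the person
#' parameter onto a T-score scale (mean approximately 50, SD approximately
#' 10). The official lookup table is distributed with the instrument manual
#' and is not bundled here; supply it as a two-column table, or use
#' [passthrough_rasch_table()] when only a monotone index is needed.
#'
#' @param sums Integer vector of raw sums covered by the table.
#' @param person_parameters Numeric vector, strictly increasing in `sums`.
#' @param scale,shift Affine transform: index = `scale` * parameter + `shift`.
#' @return An object of class `rasch_table`.
#' @export
rasch_table <- function(sums, person_parameters, scale = 1, shift = 0) {
  sums <- as.integer(sums)
  if (anyNA(sums) || anyNA(person_parameters)) stop("table must not contain NA")
  if (length(sums) != length(person_parameters)) {
    stop("`sums` and `person_parameters` must have equal length")
  }
  o <- order(sums)
  sums <- sums[o]
  person_parameters <- as.numeric(person_parameters)[o]
  if (any(duplicated(sums))) stop("duplicate raw sums in table")
  if (any(diff(person_parameters) <= 0)) {
    stop("person parameters must be strictly increasing in the raw sum")
  }
  structure(list(sums = sums, person_parameters = person_parameters,
                 scale = as.numeric(scale), shift = as.numeric(shift)),
            class = "rasch_table")
}

#' Identity (passthrough) Rasch table
#'
#' A convenience table whose person parameter equals the raw sum and whose
#' transform is the identity, giving index = raw sum. Sufficient whenever a
#' strictly monotone index is all that is required (the item-score mapping
#' algorithms never need an index at all).
#'
#' @return A `rasch_table` covering sums 10..50.
#' @export
passthrough_rasch_table <- function() {
  rasch_table(10:50, 10:50, scale = 1, shift = 0)
}

#' Read a Rasch lookup table from CSV
#'
#' Expects a header and two columns, `sum` and `person_parameter`.
#'
#' @param path CSV file path.
#' @param scale,shift Affine transform constants (see [rasch_table()]).
#' @param delimiter Field delimiter.
#' @return A `rasch_table`.
#' @export
read_rasch_table <- function(path, scale = 1, shift = 0, delimiter = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter)
  need <- c("sum", "person_parameter")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Rasch table lacks column(s): ", paste(miss, collapse = ", "))
  rasch_table(df$sum, df$person_parameter, scale = scale, shift = shift)
}

#' KIDSCREEN-10 index from a raw sum
#'
#' Applies the lookup + affine T-transform of a [rasch_table()] to a raw sum
#' score. Strictly increasing in the sum for any valid table.
#'
#' @param sum Integer raw sum (or vector of sums) in the table's domain.
#' @param table A `rasch_table`.
#' @return Numeric index value(s).
#' @export
#' @examples
#' index_from_sum(30, passthrough_rasch_table())
index_from_sum <- function(sum, table) {
  if (!inherits(table, "rasch_table")) stop("`table` must be a rasch_table")
  idx <- match(as.integer(sum), table$sums)
  if (anyNA(idx)) {
    stop("raw sum(s) outside table domain: ",
         paste(sum[is.na(idx)], collapse = ", "))
  }
  table$scale * table$person_parameters[idx] + table$shift
}

#' Assemble a paired KIDSCREEN-10 / CHU9D dataset
#'
#' Validates a respondent-level data frame for use in estimation and
#' validation: the ten item columns `ks_i1` .. `ks_i10` (ordinal 1-5, higher
#' = better), optionally `ks_index`, `age` (11-17), `gender` (0/1) and the
#' observed CHU9D utility `chu9d`. Observed utilities must lie within the
#' value set's range (default floor 0.33, the Australian adolescent tariff).
#' Complete cases only; offending rows are reported by row number.
#'
#' @param df Data frame of respondent records.
#' @param reverse_coded Items to reverse-code at ingest (see
#'   [validate_responses()]).
#' @param utility_floor,utility_ceiling Bounds of admissible observed
#'   utilities (defaults: the AU tariff range 0.33 to 1).
#' @param require_utility If `TRUE`, a `chu9d` column is mandatory
#'   (estimation/validation use); if `FALSE` the dataset may be
#'   predictor-only (mapping use).
#' @param provenance Free-text label recorded on the result.
#' @return The validated data frame with class `paired_dataset` and a
#'   `provenance` attribute.
#' @export
paired_dataset <- function(df, reverse_coded = character(),
                           utility_floor = 0.33, utility_ceiling = 1,
                           require_utility = FALSE, provenance = "user") {
  df <- as.data.frame(df)
  items <- names(ks_items())
  miss <- setdiff(items, names(df))
  if (length(miss)) stop("missing item column(s): ", paste(miss, collapse = ", "))
  if (require_utility && !("chu9d" %in% names(df))) {
    stop("missing required column: chu9d")
  }
  errors <- character()
  if (nrow(df)) {
    for (it in items) {
      v <- df[[it]]
      if (!is.numeric(v)) {
        errors <- c(errors, paste0("column ", it, " is not numeric"))
        next
      }
      bad <- which(is.na(v) | v != floor(v) | v < 1 | v > 5)
      if (length(bad)) {
        errors <- c(errors, paste0("row ", bad, ": invalid ",
                                   toupper(sub("ks_i", "KS_I", it)),
                                   " level (", v[bad], ")"))
      }
    }
    if ("chu9d" %in% names(df)) {
      u <- df$chu9d
      bad <- which(is.na(u) | u < utility_floor | u > utility_ceiling)
      if (length(bad)) {
        errors <- c(errors, paste0("row ", bad, ": observed chu9d (", u[bad],
                                   ") outside [", utility_floor, ", ",
                                   utility_ceiling, "]"))
      }
    }
    if ("age" %in% names(df)) {
      bad <- which(!is.na(df$age) & (df$age < 11 | df$age > 17))
      if (length(bad)) {
        errors <- c(errors, paste0("row ", bad, ": age (", df$age[bad],
                                   ") outside declared range 11-17"))
      }
    }
    if ("gender" %in% names(df)) {
      bad <- which(!is.na(df$gender) & !(df$gender %in% c(0, 1)))
      if (length(bad)) {
        errors <- c(errors, paste0("row ", bad, ": gender must be 0/1"))
      }
    }
  }
  if (length(errors)) {
    stop("invalid paired dataset:\n  ",
         paste(utils::head(errors, 20L), collapse = "\n  "),
         if (length(errors) > 20L) sprintf("\n  ... and %d more", length(errors) - 20L))
  }
  if (length(reverse_coded) && nrow(df)) {
    bad_rc <- setdiff(reverse_coded, items)
    if (length(bad_rc)) stop("unknown reverse-coded item(s): ",
                             paste(bad_rc, collapse = ", "))
    for (it in reverse_coded) df[[it]] <- 6L - df[[it]]
  }
  structure(df, class = c("paired_dataset", "data.frame"),
            provenance = provenance)
}
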