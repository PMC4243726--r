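# Delimited-text ingest and output for respondent records and predictions.

#' Read respondent records from a delimited text file
#'
#' Expects a header with the item columns `ks_i1` .. `ks_i10` and optionally
#' `ks_index`, `age`, `gender` and `chu9d`. All validation failures are
#' reported with file line numbers (header = line 1). An empty file with a
#' header yields an empty dataset with a warning.
#'
#' @param path File path.
#' @param delimiter Field delimiter (default comma).
#' @param reverse_coded Items to reverse-code at ingest.
#' @param utility_floor,utility_ceiling Admissible observed utility range.
#' @param require_utility Require a `chu9d` column.
#' @return A [paired_dataset()].
#' @export
read_paired_csv <- function(path, delimiter = ",",
                            reverse_coded = character(),
                            utility_floor = 0.33, utility_ceiling = 1,
                            require_utility = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE)
  if (!nrow(df)) warning("no data rows in ", path, " (header only)")
  ds <- tryCatch(
    paired_dataset(df, reverse_coded = reverse_coded,
                   utility_floor = utility_floor,
                   utility_ceiling = utility_ceiling,
                   require_utility = require_utility,
                   provenance = path),
    error = function(e) {
      # report data-row indices as file line numbers (header is line 1)
      msg <- gsub("row (\\d+):", "line \\1:", conditionMessage(e))
      m <- gregexpr("(?<=line )\\d+", msg, perl = TRUE)
      regmatches(msg, m) <- lapply(regmatches(msg, m),
                                   function(x) as.integer(x) + 1L)
      stop(path, ": ", msg, call. = FALSE)
    })
  ds
}

#' Write predictions to CSV
#'
#' Writes the input records' predictions (raw and truncated) as
#' comma-delimited text at a configurable decimal precision.
#'
#' @param predictions A `chu9d_predictions` object (see [predict_chu9d()]).
#' @param path Output file path.
#' @param precision Decimal places for the printed utilities (default 6).
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path, precision = 6L) {
  stopifnot(inherits(predictions, "chu9d_predictions"))
  out <- data.frame(
    raw = formatC(predictions$raw, digits = precision, format = "f"),
    truncated = formatC(predictions$truncated, digits = precision, format = "f"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a paired/synthetic dataset to CSV
#'
#' @param data Data frame (e.g. from [simulate_paired_data()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
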