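# Cohort CSV dialect: UTF-8, comma-separated, mandatory header, one row
# per patient, lower-snake-case enum tokens, booleans as true/false,
# missing values as the empty string.

.dfu_csv_true <- "true"
.dfu_csv_false <- "false"

#' Write a cohort to CSV
#'
#' Serializes a cohort in the package's CSV dialect. Logical columns are
#' written as `true`/`false`, missing values as empty strings, numerics
#' with full precision so a write/read round trip preserves every field
#' value exactly.
#'
#' @param cohort a [dfu_cohort()] or compatible data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_cohort_csv()]
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  df <- as.data.frame(cohort)[, .dfu_cols, drop = FALSE]
  for (col in .dfu_logical_cols) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                        ifelse(df[[col]], .dfu_csv_true, .dfu_csv_false))
  }
  for (col in .dfu_numeric_cols) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                        format(df[[col]], digits = 15, trim = TRUE,
                               scientific = FALSE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses a cohort written in the package's CSV dialect. Missing
#' mandatory columns and unknown enum/boolean tokens are hard errors
#' naming the offending rows and fields. Rows with a missing value in any
#' classifier input or outcome column are dropped (complete-case filter)
#' with a message to standard error listing how many and which rows; an
#' empty cohort after filtering is an error.
#'
#' @param path CSV file path.
#' @param provenance provenance label for the resulting cohort; defaults
#'   to the file name.
#' @return A [dfu_cohort()].
#' @seealso [write_cohort_csv()]
#' @export
read_cohort_csv <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  miss <- setdiff(.dfu_cols, names(raw))
  if (length(miss) > 0L) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  for (col in names(.dfu_enum_levels)) {
    v <- raw[[col]]
    bad <- !is.na(v) & !(v %in% .dfu_enum_levels[[col]])
    if (any(bad)) {
      stop(sprintf(
        "unknown token(s) in column '%s' at row(s) %s: %s",
        col, paste(which(bad), collapse = ", "),
        paste(sQuote(unique(v[bad])), collapse = ", ")
      ))
    }
  }
  for (col in .dfu_logical_cols) {
    v <- raw[[col]]
    bad <- !is.na(v) & !(v %in% c(.dfu_csv_true, .dfu_csv_false))
    if (any(bad)) {
      stop(sprintf(
        "column '%s' must be %s/%s; offending row(s): %s",
        col, .dfu_csv_true, .dfu_csv_false,
        paste(which(bad), collapse = ", ")
      ))
    }
    raw[[col]] <- v == .dfu_csv_true
  }
  for (col in .dfu_numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(v)
    if (any(bad)) {
      stop(sprintf("column '%s' must be numeric; offending row(s): %s",
                   col, paste(which(bad), collapse = ", ")))
    }
    raw[[col]] <- v
  }
  complete <- stats::complete.cases(raw[, .dfu_cols, drop = FALSE])
  if (any(!complete)) {
    message(sprintf(
      "read_cohort_csv: dropped %d incomplete row(s) (complete-case filter): %s",
      sum(!complete), paste(which(!complete), collapse = ", ")
    ))
    raw <- raw[complete, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("no complete records left after filtering")
  dfu_cohort(raw, provenance = provenance)
}
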