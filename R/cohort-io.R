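#' Read a cohort from CSV
#'
#' Reads a comma-separated, UTF-8 cohort file with a mandatory header row.
#' Empty cells and the literal string `"NA"` both parse as missing. Logical
#' columns accept `yes`/`no` (as written by [write_cohort()]) as well as
#' `TRUE`/`FALSE`.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping schema column names
#'   to the header names used in the file, e.g. `c(hb = "haemoglobin")`, for
#'   files with alternate headers.
#' @param name Cohort label; defaults to the file name.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(path, col_map = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || any(names(col_map) == "")) {
      stop("`col_map` must be a fully named character vector")
    }
    for (schema_name in names(col_map)) {
      file_name <- col_map[[schema_name]]
      if (!file_name %in% names(raw)) {
        stop("mapped column not found in file: ", file_name)
      }
      names(raw)[names(raw) == file_name] <- schema_name
    }
  }
  missing_cols <- setdiff(names(cohort_schema()), names(raw))
  if (length(missing_cols) > 0) {
    stop("file lacks mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  cohort(raw[names(cohort_schema())], name = name)
}

#' Write a cohort to CSV
#'
#' Writes the cohort in the canonical column order with logicals encoded as
#' `yes`/`no` and missing values as empty cells, so that
#' `read_cohort(write_cohort(x))` reproduces `x` field-for-field including
#' missingness. Output is byte-stable for a given cohort.
#'
#' @param x A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           ifelse(out[[col]], "yes", "no"))
    } else if (is.factor(out[[col]])) {
      out[[col]] <- as.character(out[[col]])
    } else if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           vapply(out[[col]], format, character(1),
                                  digits = 17, trim = TRUE, scientific = FALSE))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
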