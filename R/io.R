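#' Read an event table
#'
#' Events are UTF-8 comma-delimited with a header row and columns
#' `patient_id,event_date,raw_code`; dates are ISO-8601 (`YYYY-MM-DD`).
#' Unknown extra columns are ignored with a warning; a missing required
#' column or an unparseable date is an error naming the first offending
#' data row (1-based, header excluded). Row order is preserved.
#'
#' @param path file path.
#' @return `data.frame` with `patient_id` (character), `event_date`
#'   (`Date`), `raw_code` (character).
#' @export
readEvents <- function(path) {
  df <- readDelimited(path, c("patient_id", "event_date", "raw_code"))
  if (nrow(df) && any(!nzchar(df$raw_code)))
    stop("empty raw_code at row ", which(!nzchar(df$raw_code))[1L])
  df$event_date <- parseDateColumn(df$event_date, "event_date")
  df
}

#' Read a patient table
#'
#' Columns `patient_id,birth_date,sex,ethnicity`; duplicate patient ids
#' are an error naming the row of the second occurrence.
#'
#' @param path file path.
#' @return `data.frame` with `patient_id`, `birth_date` (`Date`), `sex`,
#'   `ethnicity`.
#' @export
readPatients <- function(path) {
  df <- readDelimited(path, c("patient_id", "birth_date", "sex", "ethnicity"))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id at row ",
         which(duplicated(df$patient_id))[1L])
  df$birth_date <- parseDateColumn(df$birth_date, "birth_date")
  df
}

readDelimited <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[required]
  }
  df[required]
}

parseDateColumn <- function(x, col) {
  d <- parseIsoDate(x)
  if (anyNA(d))
    stop("unparseable ", col, " at row ", which(is.na(d))[1L], ": '",
         x[which(is.na(d))[1L]], "'")
  d
}

#' Write canonical event / patient tables
#'
#' Writers emit the exact canonical form the readers accept, so
#' `write(read(x))` is byte-identical for canonicalised files.
#'
#' @param events,patients data frames as returned by the readers.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEvents <- function(events, path) {
  df <- data.frame(patient_id = events$patient_id,
                   event_date = format(events$event_date, "%Y-%m-%d"),
                   raw_code = events$raw_code)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeEvents
#' @export
writePatients <- function(patients, path) {
  df <- data.frame(patient_id = patients$patient_id,
                   birth_date = format(patients$birth_date, "%Y-%m-%d"),
                   sex = patients$sex, ethnicity = patients$ethnicity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a diagnosis-definition code list
#'
#' One code per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of codes.
#' @export
readCodeList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname readCodeList
#' @param codes character vector to write.
#' @export
writeCodeList <- function(codes, path) {
  writeLines(codes, path)
  invisible(path)
}
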