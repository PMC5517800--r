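#' Read raw medication entries from a delimited or JSON-lines file
#'
#' Expects columns/keys `name_text` (required), `sig_text`, `source` and
#' `dose_text`. Missing `source` defaults to `VA_PRESCRIBED`.
#'
#' @param path input file.
#' @param format `"csv"`, `"tsv"` or `"jsonl"`; guessed from the extension
#'   when omitted.
#' @return list of [raw_medication_entry()] objects.
#' @export
read_medication_entries <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", jsonl = "jsonl", ndjson = "jsonl", "csv")
  }
  format <- match.arg(format, c("csv", "tsv", "jsonl"))
  rows <- if (format == "jsonl") {
    lapply(Filter(nzchar, readLines(path, warn = FALSE)),
           jsonlite::fromJSON, simplifyVector = TRUE)
  } else {
    df <- read.csv(path, sep = if (format == "tsv") "\t" else ",",
                   stringsAsFactors = FALSE, colClasses = "character")
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  lapply(rows, function(r) {
    raw_medication_entry(
      name_text = r$name_text,
      sig_text = if (is.null(r$sig_text) || is.na(r$sig_text)) "" else r$sig_text,
      source = if (is.null(r$source) || !nzchar(r$source)) "VA_PRESCRIBED"
               else r$source,
      dose_text = if (is.null(r$dose_text) || is.na(r$dose_text)) ""
                  else r$dose_text)
  })
}

parsed_to_json <- function(p) {
  jsonlite::toJSON(list(
    raw = unclass(p$raw),
    dose = if (is.null(p$dose)) NULL else as.list(p$dose),
    conflict_dose = if (is.null(p$conflict_dose)) NULL
                    else as.list(p$conflict_dose),
    quantity = p$quantity,
    schedule = unclass(p$schedule),
    total_daily_dose = p$total_daily_dose,
    status = as.list(p$status)
  ), auto_unbox = TRUE, null = "null", digits = NA)
}

#' Write parsed medications as JSON-lines
#' @param parsed list of [parse_entry()] results.
#' @param path output file.
#' @export
write_parsed_medications <- function(parsed, path) {
  writeLines(vapply(parsed, parsed_to_json, character(1)), path)
  invisible(path)
}

#' Summarize parsed medications as a table
#'
#' One row per entry: drug name text, extracted dose/unit/schedule, total
#' daily dose and status flags — the display form of a parse run.
#'
#' @param parsed list of [parse_entry()] results.
#' @return data frame.
#' @export
parsed_summary <- function(parsed) {
  do.call(rbind, lapply(parsed, function(p) {
    data.frame(
      name_text = p$raw$name_text,
      dose = if (is.null(p$dose)) NA_real_ else p$dose$value,
      unit = if (is.null(p$dose)) NA_character_ else p$dose$unit,
      schedule = p$schedule$code,
      daily_dose = if (is.null(p$total_daily_dose)) NA_real_
                   else p$total_daily_dose$value,
      status = paste(p$status, collapse = "|"),
      stringsAsFactors = FALSE)
  }))
}

#' Parse-failure report
#'
#' The operational health metric of a parse run: how often a total daily
#' dose could not be determined, and how often each status flag fired.
#'
#' @param parsed list of [parse_entry()] results.
#' @return list with `n`, `n_no_daily_dose`, `failure_rate` and
#'   `flag_counts` (named integer vector).
#' @export
parse_report <- function(parsed) {
  n <- length(parsed)
  no_tdd <- sum(vapply(parsed, function(p) is.null(p$total_daily_dose),
                       logical(1)))
  flags <- unlist(lapply(parsed, `[[`, "status"))
  list(n = n, n_no_daily_dose = no_tdd,
       failure_rate = if (n) no_tdd / n else NA_real_,
       flag_counts = if (length(flags)) table(flags) else table(character(0)))
}

#' Read a patient cohort from JSON-lines
#'
#' One patient snapshot per line with keys `patient_id`, `age`,
#' `icd9_codes`, `appointment_date`, `clinic_name`, `medications` (array of
#' raw-entry objects) and `contact`, as written by [write_fixtures()].
#'
#' @param path JSON-lines file.
#' @return list of [patient_snapshot()] objects.
#' @export
read_patient_cohort <- function(path) {
  lapply(Filter(nzchar, readLines(path, warn = FALSE)), function(line) {
    j <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    meds <- lapply(j$medications, function(m) {
      raw_medication_entry(m$name_text,
                           if (is.null(m$sig_text)) "" else m$sig_text,
                           if (is.null(m$source)) "VA_PRESCRIBED" else m$source,
                           if (is.null(m$dose_text)) "" else m$dose_text)
    })
    patient_snapshot(j$patient_id, j$age,
                     unlist(j$icd9_codes, use.names = FALSE),
                     j$appointment_date,
                     if (is.null(j$clinic_name)) "" else j$clinic_name,
                     meds,
                     if (is.null(j$contact)) "" else j$contact)
  })
}
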