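#' Create a raw medication entry
#'
#' A raw entry is the immutable Drug Name / Sig free-text pair as retrieved
#' from the EHR. The `name` field frequently embeds dose and decorations, the
#' `sig` field carries the administration instruction, and the dedicated
#' `dose` field is typically blank in practice, so it is retained only for
#' completeness. `source` distinguishes the real-time VistA feeds
#' (`VA_PRESCRIBED`, `NON_VA`) from the data-warehouse dialect (`CDW`), whose
#' schedule strings are already standardized abbreviations.
#'
#' @param name_text non-empty free text of the Drug Name field.
#' @param sig_text free text of the Sig (schedule/instruction) field; may be
#'   empty.
#' @param source one of `"VA_PRESCRIBED"`, `"NON_VA"`, `"CDW"`.
#' @param dose_text the (usually blank) dose field.
#' @return an object of class `raw_medication_entry`.
#' @examples
#' raw_medication_entry("GABAPENTIN 300 MG, CAP",
#'                      "TAKE ONE CAPSULE BY MOUTH THREE TIMES A DAY")
#' @export
raw_medication_entry <- function(name_text, sig_text = "",
                                 source = c("VA_PRESCRIBED", "NON_VA", "CDW"),
                                 dose_text = "") {
  source <- match.arg(source)
  stopifnot(is.character(name_text), length(name_text) == 1L,
            !is.na(name_text), nzchar(name_text))
  if (is.na(sig_text)) sig_text <- ""
  if (is.na(dose_text)) dose_text <- ""
  structure(list(name_text = name_text, sig_text = as.character(sig_text),
                 source = source, dose_text = as.character(dose_text)),
            class = "raw_medication_entry")
}

#' Extract dose matches from free text
#'
#' Scans `text` left to right for non-overlapping dose strings: an optional
#' opening parenthesis, a decimal number, optional whitespace, a unit
#' (MG, MCG or MEQ by default, case-insensitively) and an optional closing
#' parenthesis — accepting forms like `"32.5 MG"`, `"18MCG"` and
#' `"(1.5 meq)"`. Matching never converts between units.
#'
#' @param text a character string (may be empty or `NA`).
#' @param patterns a pattern registry, see [default_patterns()].
#' @return a data frame with one row per match and columns `value` (numeric,
#'   positive), `unit` (canonical uppercase), `start`/`end` (1-based inclusive
#'   character positions of the matched substring) and `match` (the substring
#'   itself). Zero rows when nothing matches.
#' @examples
#' extract_dose("GABAPENTIN 300 MG, CAP")
#' extract_dose("(1.5 meq)")
#' extract_dose("PROPRANOLOL TAB")
#' @export
extract_dose <- function(text, patterns = default_patterns()) {
  empty <- data.frame(value = numeric(0), unit = character(0),
                      start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE)
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(empty)
  rx <- dose_regex(patterns)
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  matches <- substring(text, starts, ends)
  stripped <- gsub("[()]", "", matches)
  unit_rx <- paste0("(?i)(", paste(patterns$dose_units, collapse = "|"),
                    ")\\s*$")
  units <- toupper(sub(paste0(".*?", unit_rx), "\\1", stripped, perl = TRUE))
  values <- as.numeric(sub(unit_rx, "", stripped, perl = TRUE))
  data.frame(value = values, unit = units, start = starts, end = ends,
             match = matches, stringsAsFactors = FALSE)
}

#' Construct a schedule code
#'
#' Schedule abbreviations carry fixed administrations-per-day multipliers:
#' QD, QAM and QHS are once daily, BID and Q12H twice, TID three times,
#' QID four and Q4H six. `WEEKLY_DAYS` carries a per-week count instead;
#' `PRN`, `AS_DIRECTED` and `UNKNOWN` carry no multiplier, so no total daily
#' dose can be computed from them.
#'
#' @param code one of `r paste(SCHEDULE_CODES, collapse = ", ")`.
#' @param per_week number of administrations per week; required (and only
#'   allowed) for `WEEKLY_DAYS`.
#' @return an object of class `schedule_code` with fields `code`, `per_day`
#'   (integer or `NA`) and `per_week` (integer or `NA`).
#' @export
schedule_code <- function(code, per_week = NA_integer_) {
  code <- match.arg(code, SCHEDULE_CODES)
  per_day <- if (code %in% names(PER_DAY_MAP)) PER_DAY_MAP[[code]] else NA_integer_
  if (code == "WEEKLY_DAYS") {
    stopifnot(is.numeric(per_week), !is.na(per_week), per_week >= 1)
    per_week <- as.integer(per_week)
  } else {
    per_week <- NA_integer_
  }
  structure(list(code = code, per_day = per_day, per_week = per_week),
            class = "schedule_code")
}

#' Extract a schedule from sig text
#'
#' Applies, case-insensitively and in order of clinical precedence:
#' as-needed phrases (`PRN` — an as-needed medication has no fixed daily
#' schedule even when a frequency phrase or cap is also present), then the
#' frequency-phrase grammar (bedtime / once daily / twice daily / three times
#' a day / four times a day by default), then day-of-week lists
#' (`WEEKLY_DAYS`, with `per_week` = number of distinct weekday names), then
#' as-directed phrases. Anything else is `UNKNOWN`.
#'
#' @inheritParams extract_dose
#' @return a [schedule_code()].
#' @examples
#' extract_schedule("TAKE ONE CAPSULE BY MOUTH THREE TIMES A DAY")
#' extract_schedule("20MG MOUTH MONDAY, WEDNESDAY AND FRIDAY")
#' @export
extract_schedule <- function(text, patterns = default_patterns()) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    return(schedule_code("UNKNOWN"))
  }
  for (p in patterns$prn_phrases) {
    if (grepl(paste0("\\b", phrase_regex(p), "\\b"), text,
              ignore.case = TRUE, perl = TRUE)) {
      return(schedule_code("PRN"))
    }
  }
  rx <- schedule_regex(patterns)
  m <- regexpr(rx, text, ignore.case = TRUE, perl = TRUE)
  if (m[1] != -1L) {
    hit <- collapse_ws(tolower(regmatches(text, m)))
    idx <- match(hit, tolower(names(patterns$schedule_phrases)))
    if (!is.na(idx)) {
      return(schedule_code(unname(patterns$schedule_phrases[idx])))
    }
  }
  days <- vapply(patterns$weekday_names, function(d) {
    grepl(paste0("\\b", d, "\\b"), text, ignore.case = TRUE, perl = TRUE)
  }, logical(1))
  if (any(days)) {
    return(schedule_code("WEEKLY_DAYS", per_week = sum(days)))
  }
  for (p in patterns$as_directed_phrases) {
    if (grepl(paste0("\\b", phrase_regex(p), "\\b"), text,
              ignore.case = TRUE, perl = TRUE)) {
      return(schedule_code("AS_DIRECTED"))
    }
  }
  schedule_code("UNKNOWN")
}

#' Extract a quantity-per-administration multiplier
#'
#' Maps a leading quantity word (ONE..FOUR, or a digit 1-4) immediately
#' preceding a unit-of-administration word (TABLET, CAPSULE, TAB, CAP and
#' plurals) to its integer value. Defaults to 1 when no such construct is
#' present — "TAKE ONE CAPSULE" and a bare "162MG MOUTH" both administer one
#' unit at a time.
#'
#' @inheritParams extract_dose
#' @return a positive integer.
#' @export
extract_quantity <- function(text, patterns = default_patterns()) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(1L)
  words <- c(names(patterns$quantity_words), as.character(patterns$quantity_words))
  vals <- c(unname(patterns$quantity_words), unname(patterns$quantity_words))
  rx <- paste0("\\b(", paste(words, collapse = "|"), ")[\\s]+(",
               paste(patterns$admin_units, collapse = "|"), ")\\b")
  m <- regexpr(rx, text, ignore.case = TRUE, perl = TRUE)
  if (m[1] == -1L) return(1L)
  qword <- toupper(sub(paste0("(?i)", rx, ".*"), "\\1",
                       substring(text, m, nchar(text)), perl = TRUE))
  idx <- match(qword, toupper(words))
  if (is.na(idx)) 1L else as.integer(vals[idx])
}

#' Compute a total daily dose
#'
#' Total daily dose = per-administration dose x quantity per administration x
#' administrations per day. It is only defined when the schedule carries a
#' per-day multiplier; as-needed, as-directed, weekly and unknown schedules
#' yield `NULL` (a 3-times-a-week drug is deliberately not averaged into a
#' fractional daily dose). Units are never interconverted: the result carries
#' the dose's unit.
#'
#' @param dose a one-row dose match as returned by [extract_dose()], or a
#'   list with `value` and `unit`.
#' @param quantity positive integer units per administration.
#' @param schedule a [schedule_code()].
#' @return `list(value=, unit=)`, or `NULL` when undefined.
#' @examples
#' total_daily_dose(list(value = 300, unit = "MG"), 1, schedule_code("TID"))
#' total_daily_dose(list(value = 50, unit = "MG"), 1, schedule_code("PRN"))
#' @export
total_daily_dose <- function(dose, quantity, schedule) {
  stopifnot(inherits(schedule, "schedule_code"),
            is.numeric(quantity), quantity >= 1)
  if (is.null(dose) || is.na(schedule$per_day)) return(NULL)
  list(value = dose$value * quantity * schedule$per_day, unit = dose$unit)
}

#' Parse a raw medication entry
#'
#' Runs dose extraction over both the Drug Name and Sig fields, and schedule
#' and quantity extraction over the Sig field, then assembles a structured
#' parse. When both fields carry a dose, the Sig dose wins (it states the
#' administered amount) and, if the two disagree in value or unit, the losing
#' match is kept in `conflict_dose` and `DOSE_CONFLICT` is flagged. Within a
#' field the leftmost dose wins; later matches are retained in `extra_doses`
#' for diagnostics. Entries from the data-warehouse dialect (`source =
#' "CDW"`) have their sig matched directly against the standardized schedule
#' abbreviations; an empty or `NULL` sig maps to `UNKNOWN`.
#'
#' Parsing never fails: every input yields a `parsed_medication` whose `raw`
#' field retains the input verbatim (the display fallback when a total daily
#' dose cannot be determined), with failure expressed through status flags:
#' \describe{
#'   \item{OK}{total daily dose defined and no dose conflict.}
#'   \item{NO_DOSE}{no dose found in either field.}
#'   \item{NO_SCHEDULE}{schedule is UNKNOWN or AS_DIRECTED.}
#'   \item{DOSE_CONFLICT}{name and sig doses disagree.}
#'   \item{PRN / WEEKLY / AS_DIRECTED}{the corresponding schedule semantics.}
#' }
#'
#' @param entry a [raw_medication_entry()].
#' @inheritParams extract_dose
#' @return an object of class `parsed_medication` with fields `raw`, `dose`
#'   (one-row data frame with `source_field`, or `NULL`), `conflict_dose`,
#'   `extra_doses`, `quantity`, `schedule`, `total_daily_dose`
#'   (`list(value, unit)` or `NULL`) and `status` (character vector).
#' @examples
#' e <- raw_medication_entry("GABAPENTIN 300 MG, CAP",
#'                           "TAKE ONE CAPSULE BY MOUTH THREE TIMES A DAY")
#' p <- parse_entry(e)
#' p$total_daily_dose
#' @export
parse_entry <- function(entry, patterns = default_patterns()) {
  stopifnot(inherits(entry, "raw_medication_entry"))
  name_doses <- extract_dose(entry$name_text, patterns)
  sig_doses <- extract_dose(entry$sig_text, patterns)
  if (nrow(name_doses)) name_doses$source_field <- "NAME"
  if (nrow(sig_doses)) sig_doses$source_field <- "SIG"

  if (entry$source == "CDW") {
    sig <- toupper(trimws(entry$sig_text))
    schedule <- if (nzchar(sig) && sig != "NULL" &&
                    sig %in% patterns$cdw_schedule_codes) {
      schedule_code(sig)
    } else {
      schedule_code("UNKNOWN")
    }
  } else {
    schedule <- extract_schedule(entry$sig_text, patterns)
  }
  quantity <- extract_quantity(entry$sig_text, patterns)

  dose <- NULL
  conflict <- NULL
  extra <- rbind(
    if (nrow(sig_doses) > 1L) sig_doses[-1L, , drop = FALSE],
    if (nrow(name_doses) > 1L) name_doses[-1L, , drop = FALSE]
  )
  if (nrow(sig_doses)) {
    dose <- sig_doses[1L, , drop = FALSE]
    if (nrow(name_doses)) {
      nd <- name_doses[1L, , drop = FALSE]
      if (nd$value != dose$value || nd$unit != dose$unit) conflict <- nd
    }
  } else if (nrow(name_doses)) {
    dose <- name_doses[1L, , drop = FALSE]
  }

  tdd <- total_daily_dose(dose, quantity, schedule)

  status <- character(0)
  if (is.null(dose)) status <- c(status, "NO_DOSE")
  if (schedule$code %in% c("UNKNOWN", "AS_DIRECTED")) {
    status <- c(status, "NO_SCHEDULE")
  }
  if (!is.null(conflict)) status <- c(status, "DOSE_CONFLICT")
  if (schedule$code == "PRN") status <- c(status, "PRN")
  if (schedule$code == "WEEKLY_DAYS") status <- c(status, "WEEKLY")
  if (schedule$code == "AS_DIRECTED") status <- c(status, "AS_DIRECTED")
  if (!is.null(tdd) && is.null(conflict)) status <- c(status, "OK")

  structure(list(raw = entry, dose = dose, conflict_dose = conflict,
                 extra_doses = if (is.null(extra)) NULL else extra,
                 quantity = quantity, schedule = schedule,
                 total_daily_dose = tdd, status = status),
            class = "parsed_medication")
}

#' @export
print.parsed_medication <- function(x, ...) {
  cat("<parsed_medication>\n")
  cat("  name:", x$raw$name_text, "\n")
  cat("  sig: ", x$raw$sig_text, "\n")
  if (!is.null(x$dose)) {
    cat(sprintf("  dose: %g %s (from %s)\n",
                x$dose$value, x$dose$unit, x$dose$source_field))
  } else {
    cat("  dose: <none>\n")
  }
  cat("  schedule:", x$schedule$code,
      if (!is.na(x$schedule$per_day)) sprintf("(%d/day)", x$schedule$per_day)
      else if (!is.na(x$schedule$per_week))
        sprintf("(%d/week)", x$schedule$per_week)
      else "", "\n")
  if (!is.null(x$total_daily_dose)) {
    cat(sprintf("  total daily dose: %g %s\n",
                x$total_daily_dose$value, x$total_daily_dose$unit))
  } else {
    cat("  total daily dose: <undetermined>\n")
  }
  cat("  status:", paste(x$status, collapse = ", "), "\n")
  invisible(x)
}
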