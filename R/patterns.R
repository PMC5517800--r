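#' The pattern registry
#'
#' All text-matching knowledge used by the sig parser lives in one registry
#' object so that new dose units, schedule phrases or quantity words observed
#' in production data can be added as configuration, without touching code.
#' `default_patterns()` returns the built-in registry; `read_patterns()` loads
#' a YAML or JSON file whose top-level keys override the corresponding
#' registry entries (keys not present keep their defaults).
#'
#' The registry fields are:
#' \describe{
#'   \item{dose_units}{character vector of unit spellings (canonical form,
#'     matched case-insensitively): `MG`, `MCG`, `MEQ`.}
#'   \item{schedule_phrases}{named character vector mapping a frequency phrase
#'     (words separated by single spaces; any run of whitespace is accepted
#'     between words when matching) to its schedule code, e.g.
#'     `"three times a day" = "TID"`.}
#'   \item{prn_phrases, as_directed_phrases}{phrases that flag as-needed and
#'     as-directed instructions.}
#'   \item{weekday_names}{the seven day names recognized in day-of-week
#'     schedules.}
#'   \item{quantity_words}{named integer vector mapping quantity words to
#'     multipliers (`ONE` = 1 ... `FOUR` = 4).}
#'   \item{admin_units}{unit-of-administration words a quantity must precede
#'     (TABLET, CAPSULE, TAB, CAP and plurals).}
#'   \item{cdw_schedule_codes}{the standardized schedule abbreviations emitted
#'     by the data-warehouse dialect, mapped straight through.}
#'   \item{form_suffixes}{dose-form tokens stripped from the tail of drug
#'     names during normalization.}
#' }
#'
#' @param path path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @return a list of class `sig_patterns`.
#' @examples
#' p <- default_patterns()
#' names(p$schedule_phrases)
#' @export
default_patterns <- function() {
  structure(list(
    dose_units = c("MG", "MCG", "MEQ"),
    schedule_phrases = c(
      "bedtime"           = "QHS",
      "once daily"        = "QD",
      "twice daily"       = "BID",
      "three times a day" = "TID",
      "four times a day"  = "QID"
    ),
    prn_phrases = c("as needed", "prn"),
    as_directed_phrases = c("as directed"),
    weekday_names = c("MONDAY", "TUESDAY", "WEDNESDAY", "THURSDAY",
                      "FRIDAY", "SATURDAY", "SUNDAY"),
    quantity_words = c(ONE = 1L, TWO = 2L, THREE = 3L, FOUR = 4L),
    admin_units = c("TABLETS", "TABLET", "TABS", "TAB",
                    "CAPSULES", "CAPSULE", "CAPS", "CAP"),
    cdw_schedule_codes = c("QD", "QAM", "QHS", "BID", "TID", "QID",
                           "Q4H", "Q12H"),
    form_suffixes = c("TAB", "TABS", "TABLET", "CAP", "CAPS", "CAPSULE",
                      "SA", "EC", "CR", "XR", "SL", "ER", "ODT")
  ), class = "sig_patterns")
}

#' @rdname default_patterns
#' @export
read_patterns <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  pat <- unclass(default_patterns())
  for (key in intersect(names(raw), names(pat))) {
    val <- raw[[key]]
    if (key %in% c("schedule_phrases", "quantity_words")) {
      val <- unlist(val)
      if (key == "quantity_words") storage.mode(val) <- "integer"
    } else {
      val <- as.character(unlist(val))
    }
    pat[[key]] <- val
  }
  structure(pat, class = "sig_patterns")
}

# Administrations-per-day multipliers: fixed clinical semantics of the
# schedule abbreviations, not configuration.
PER_DAY_MAP <- c(QD = 1L, QAM = 1L, QHS = 1L, BID = 2L, TID = 3L,
                 QID = 4L, Q4H = 6L, Q12H = 2L)

SCHEDULE_CODES <- c(names(PER_DAY_MAP), "WEEKLY_DAYS", "PRN",
                    "AS_DIRECTED", "UNKNOWN")

# Build a character class matching one letter case-insensitively, in the
# per-letter [mM] style, and a full alternation for the configured units.
letter_class <- function(word) {
  paste0(vapply(strsplit(word, "")[[1]],
                function(ch) paste0("[", tolower(ch), toupper(ch), "]"),
                character(1)),
         collapse = "")
}

dose_regex <- function(patterns) {
  alt <- paste(vapply(patterns$dose_units, letter_class, character(1)),
               collapse = "|")
  paste0("[(]?[0-9]*[.]?[0-9]+[\\s]*(", alt, ")[)]?")
}

# "three times a day" -> "three[\s]*times[\s]*a[\s]*day"
phrase_regex <- function(phrase) {
  paste(strsplit(phrase, " ", fixed = TRUE)[[1]], collapse = "[\\s]*")
}

schedule_regex <- function(patterns) {
  paste0("(", paste(vapply(names(patterns$schedule_phrases), phrase_regex,
                           character(1)), collapse = "|"), ")")
}
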