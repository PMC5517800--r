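#' Reduce a diagnosis history to disease presence flags
#'
#' The staging store holds the minimum necessary for real-time decision
#' support: one boolean per configured disease, and nothing else — raw ICD-9
#' codes are never retained. A disease flag is true when any code's integer
#' category matches one of the disease's configured prefixes.
#'
#' @param icd9_codes character vector of dotted ICD-9 codes.
#' @param disease_panel named list mapping disease name to an integer vector
#'   of ICD-9 category prefixes; see [default_disease_panel()].
#' @return named logical vector, one entry per configured disease.
#' @examples
#' preprocess_diagnoses(c("250.60", "345.90"))
#' @export
preprocess_diagnoses <- function(icd9_codes,
                                 disease_panel = default_disease_panel()) {
  stopifnot(length(disease_panel) > 0L, !is.null(names(disease_panel)))
  codes <- drop_malformed_icd9(icd9_codes)
  vapply(disease_panel, function(prefixes) {
    icd9_category_match(codes, prefixes)
  }, logical(1))
}

#' Default five-disease panel
#'
#' A neuropathic-pain-plausible example panel (diabetes, herpes zoster,
#' chronic kidney disease, depression, seizure disorder). The panel is pure
#' configuration: deployments supply their own disease-to-prefix map.
#'
#' @return named list of integer ICD-9 category prefixes.
#' @export
default_disease_panel <- function() {
  list(diabetes = 250L,
       herpes_zoster = 53L,
       chronic_kidney_disease = 585L,
       depression = c(296L, 311L),
       seizure_disorder = 345L)
}

#' Derive prior-but-not-current medications
#'
#' From a medication prescription history, find each panel drug that has been
#' previously prescribed but is not currently prescribed, and keep only its
#' name and the date of its most recent prescription. "Currently prescribed"
#' is defined by the supplied current-medication name set.
#'
#' @param history data frame with columns `name` (base drug name, as produced
#'   by [normalize_name()]) and `date` (prescription date); rows need not be
#'   ordered. A `patient_id` column, if present, is ignored — the history is
#'   one patient's.
#' @param current character vector of currently prescribed base names.
#' @param drug_panel character vector of panel base names; history rows
#'   outside the panel are ignored.
#' @return data frame with columns `name` and `last_date`, sorted by name.
#' @examples
#' h <- data.frame(name = c("GABAPENTIN", "GABAPENTIN", "AMITRIPTYLINE"),
#'                 date = as.Date(c("2014-01-01", "2015-03-01", "2013-05-01")))
#' derive_prior_medications(h, current = "GABAPENTIN",
#'                          drug_panel = c("GABAPENTIN", "AMITRIPTYLINE"))
#' @export
derive_prior_medications <- function(history, current, drug_panel) {
  empty <- data.frame(name = character(0), last_date = as.Date(character(0)),
                      stringsAsFactors = FALSE)
  if (is.null(history) || !nrow(history)) return(empty)
  stopifnot(all(c("name", "date") %in% names(history)))
  name <- toupper(trimws(history$name))
  date <- as.Date(history$date)
  stopifnot(!anyNA(date))
  keep <- name %in% toupper(drug_panel) & !(name %in% toupper(current))
  if (!any(keep)) return(empty)
  agg <- tapply(date[keep], name[keep], max)
  out <- data.frame(name = names(agg),
                    last_date = as.Date(as.vector(agg), origin = "1970-01-01"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a staged patient record
#'
#' @param patient_id opaque identifier.
#' @param disease_flags named logical vector whose names are exactly the
#'   configured disease panel.
#' @param prior_medications data frame (`name`, `last_date`) as returned by
#'   [derive_prior_medications()]; must not contain any drug in `current`.
#' @param staged_at staging timestamp (`POSIXct`; defaults to now).
#' @param refresh_tag label of the refresh cycle that produced the record.
#' @return an object of class `staged_patient_record`.
#' @export
staged_patient_record <- function(patient_id, disease_flags,
                                  prior_medications = NULL,
                                  staged_at = Sys.time(),
                                  refresh_tag = "") {
  stopifnot(length(patient_id) == 1L, nzchar(patient_id),
            is.logical(disease_flags), !is.null(names(disease_flags)))
  if (is.null(prior_medications)) {
    prior_medications <- data.frame(name = character(0),
                                    last_date = as.Date(character(0)),
                                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "last_date") %in% names(prior_medications)))
  structure(list(patient_id = as.character(patient_id),
                 disease_flags = disease_flags,
                 prior_medications = prior_medications,
                 staged_at = staged_at, refresh_tag = refresh_tag),
            class = "staged_patient_record")
}

#' An in-memory staging store with weekly-refresh replacement semantics
#'
#' `staging_store()` creates an empty store; [stage_records()] inserts a batch
#' of records under a refresh tag, fully replacing any existing record for
#' the same patient; [query_patient()] looks a patient up in real time. The
#' store round-trips through a JSON-lines file via [write_staging_store()] /
#' [read_staging_store()] (one record per line; documented schema:
#' `patient_id`, `disease_flags` object, `prior_medications` array of
#' `{name, last_date}`, `staged_at`, `refresh_tag`).
#'
#' @return `staging_store()`: an empty store of class `staging_store`.
#' @export
staging_store <- function() {
  structure(list(records = list()), class = "staging_store")
}

#' @rdname staging_store
#' @param store a `staging_store`.
#' @param records list of [staged_patient_record()] objects.
#' @param refresh_tag tag recorded on every staged record of this batch.
#' @export
stage_records <- function(store, records, refresh_tag = format(Sys.Date())) {
  stopifnot(inherits(store, "staging_store"))
  if (inherits(records, "staged_patient_record")) records <- list(records)
  for (r in records) {
    stopifnot(inherits(r, "staged_patient_record"))
    r$refresh_tag <- refresh_tag
    store$records[[r$patient_id]] <- r
  }
  store
}

#' @rdname staging_store
#' @param patient_id id to look up.
#' @return `query_patient()`: the most recently staged record, or `NULL` when
#'   the patient has never been staged (explicitly distinguishable from a
#'   staged record whose flags are all false).
#' @export
query_patient <- function(store, patient_id) {
  stopifnot(inherits(store, "staging_store"))
  store$records[[as.character(patient_id)]]
}

#' @rdname staging_store
#' @param path JSON-lines file path.
#' @export
write_staging_store <- function(store, path) {
  stopifnot(inherits(store, "staging_store"))
  lines <- vapply(store$records, function(r) {
    jsonlite::toJSON(list(
      patient_id = r$patient_id,
      disease_flags = as.list(r$disease_flags),
      prior_medications = lapply(seq_len(nrow(r$prior_medications)),
        function(i) list(name = r$prior_medications$name[i],
                         last_date = format(r$prior_medications$last_date[i]))),
      staged_at = format(r$staged_at, "%Y-%m-%dT%H:%M:%S"),
      refresh_tag = r$refresh_tag
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname staging_store
#' @export
read_staging_store <- function(path) {
  store <- staging_store()
  for (line in readLines(path, warn = FALSE)) {
    if (!nzchar(trimws(line))) next
    j <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    pm <- if (length(j$prior_medications)) {
      data.frame(
        name = vapply(j$prior_medications, `[[`, character(1), "name"),
        last_date = as.Date(vapply(j$prior_medications, `[[`, character(1),
                                   "last_date")),
        stringsAsFactors = FALSE)
    } else NULL
    rec <- staged_patient_record(
      patient_id = j$patient_id,
      disease_flags = vapply(j$disease_flags, isTRUE, logical(1)),
      prior_medications = pm,
      staged_at = as.POSIXct(j$staged_at, format = "%Y-%m-%dT%H:%M:%S",
                             tz = ""),
      refresh_tag = j$refresh_tag)
    store$records[[rec$patient_id]] <- rec
  }
  store
}
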