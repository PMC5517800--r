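#' Create a patient snapshot
#'
#' The unit of cohort screening: one patient's scheduled appointment together
#' with the age, diagnosis codes and medication list needed to place them in
#' the recruitment grid.
#'
#' @param patient_id opaque identifier, unique within a cohort extract.
#' @param age integer years, non-negative.
#' @param icd9_codes character vector of dotted ICD-9 codes.
#' @param appointment_date a `Date` (or string coercible to one).
#' @param clinic_name clinic text label.
#' @param medications list of [raw_medication_entry()] objects.
#' @param contact opaque contact text block.
#' @return an object of class `patient_snapshot`.
#' @export
patient_snapshot <- function(patient_id, age, icd9_codes = character(0),
                             appointment_date, clinic_name = "",
                             medications = list(), contact = "") {
  stopifnot(length(patient_id) == 1L, nzchar(patient_id),
            is.numeric(age), age >= 0)
  appointment_date <- as.Date(appointment_date)
  stopifnot(!is.na(appointment_date))
  structure(list(patient_id = as.character(patient_id), age = as.integer(age),
                 icd9_codes = as.character(icd9_codes),
                 appointment_date = appointment_date,
                 clinic_name = clinic_name, medications = medications,
                 contact = contact),
            class = "patient_snapshot")
}

# Drop strings that are not plausible ICD-9 codes, warning once. V/E codes
# are valid (they just never match a numeric prefix).
drop_malformed_icd9 <- function(codes) {
  ok <- grepl("^[VvEe]?[0-9]{2,3}(\\.[0-9]{0,2})?$", trimws(codes))
  if (any(!ok)) {
    warning("skipping malformed ICD9 code(s): ",
            paste(codes[!ok], collapse = ", "), call. = FALSE)
  }
  codes[ok]
}

# Match pre-validated ICD-9 codes against integer category prefixes (the
# part before the dot).
icd9_category_match <- function(codes, prefixes) {
  if (!length(codes)) return(FALSE)
  cats <- sub("\\..*$", "", trimws(codes))
  num <- suppressWarnings(as.integer(cats))
  any(!is.na(num) & num %in% as.integer(prefixes))
}

#' Default ICD-9 prefix lists for the screening comorbidities
#'
#' Hypertension is coded under categories 401-405 (essential and secondary
#' hypertension, hypertensive heart/kidney disease) and diabetes mellitus
#' under 250. The exact lists used operationally are configurable.
#'
#' @return named list of integer prefix vectors.
#' @export
default_code_policy <- function() {
  list(hypertension = 401:405, diabetes = 250L)
}

#' Flag hypertension and diabetes from ICD-9 codes
#'
#' Scans a patient's codes for the presence or absence of hypertension and
#' diabetes; a flag is true when any code's integer category (before the dot)
#' is in the condition's prefix list.
#'
#' @param icd9_codes character vector of dotted ICD-9 codes.
#' @param code_policy list with `hypertension` and `diabetes` prefix vectors,
#'   see [default_code_policy()].
#' @return named logical vector `c(htn=, dm=)`.
#' @examples
#' comorbidity_flags(c("250.00", "401.9"))
#' @export
comorbidity_flags <- function(icd9_codes, code_policy = default_code_policy()) {
  codes <- drop_malformed_icd9(icd9_codes)
  c(htn = icd9_category_match(codes, code_policy$hypertension),
    dm = icd9_category_match(codes, code_policy$diabetes))
}

#' Count a patient's drugs of interest
#'
#' Classifies each medication with [classify_medication()] and counts the
#' distinct base names in category `OF_INTEREST` — two entries of the same
#' drug (e.g. a renewal alongside an original fill) count once.
#'
#' @param medications list of [raw_medication_entry()] objects.
#' @param formulary,policy,patterns as in [classify_medication()].
#' @return non-negative integer.
#' @export
count_drugs_of_interest <- function(medications, formulary,
                                    policy = classification_policy(),
                                    patterns = default_patterns()) {
  if (!length(medications)) return(0L)
  bases <- character(0)
  for (m in medications) {
    cl <- classify_medication(parse_entry(m, patterns), formulary, policy,
                              patterns = patterns)
    if (cl$category == "OF_INTEREST") bases <- c(bases, cl$base_name)
  }
  length(unique(bases))
}

#' Default age bands for the recruitment grid
#' @return named list of `c(lo, hi)` inclusive integer intervals.
#' @export
default_age_bands <- function() {
  list("65-74" = c(65, 74), "75-84" = c(75, 84), "85+" = c(85, Inf))
}

age_band_label <- function(age, age_bands) {
  for (lab in names(age_bands)) {
    b <- age_bands[[lab]]
    if (age >= b[1] && age <= b[2]) return(lab)
  }
  "other"
}

drug_count_label <- function(k, max_count) {
  if (k >= max_count) paste0(max_count, "+") else as.character(k)
}

#' Build a recruitment screening grid
#'
#' Filters a cohort to patients with an appointment inside the half-open date
#' window `[start, end)`, assigns each to exactly one (age band, drugs-of-
#' interest count) cell, and tallies within each cell the patients with only
#' hypertension, only diabetes, and both, from their ICD-9 codes. A patient
#' appearing more than once in the window is counted once, at their earliest
#' appointment; an age outside all configured bands goes to an explicit
#' `"other"` band rather than being dropped. Cell output ordering is
#' deterministic (band order then drug count), and the result is invariant to
#' the input ordering of the cohort.
#'
#' @param cohort list of [patient_snapshot()] objects.
#' @param window length-2 `Date` vector, half-open `[start, end)`.
#' @param age_bands named list of inclusive `c(lo, hi)` intervals, ordered;
#'   see [default_age_bands()].
#' @param formulary,policy,patterns as in [classify_medication()].
#' @param code_policy see [comorbidity_flags()].
#' @param max_drug_count drug counts at or above this value share a top
#'   overflow bucket (default 10, displayed `"10+"`).
#' @return an object of class `screening_grid`: list with `window`,
#'   `age_bands`, `drug_counts` (axis labels), `cells` (data frame
#'   `age_band`, `drug_count`, `n_total`, `n_htn_only`, `n_dm_only`,
#'   `n_both`), `assignments` (per-patient rows) and `patients` (the
#'   deduplicated in-window snapshots, keyed by id).
#' @export
build_screening_grid <- function(cohort, window,
                                 age_bands = default_age_bands(),
                                 formulary, policy = classification_policy(),
                                 code_policy = default_code_policy(),
                                 max_drug_count = 10L,
                                 patterns = default_patterns()) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, !anyNA(window), window[1] <= window[2])

  in_win <- Filter(function(p) {
    p$appointment_date >= window[1] && p$appointment_date < window[2]
  }, cohort)
  # one row per patient, earliest in-window appointment wins
  if (length(in_win)) {
    ord <- order(vapply(in_win, function(p) as.numeric(p$appointment_date),
                        numeric(1)),
                 vapply(in_win, function(p) p$patient_id, character(1)))
    in_win <- in_win[ord]
    ids <- vapply(in_win, function(p) p$patient_id, character(1))
    in_win <- in_win[!duplicated(ids)]
  }

  band_labels <- c(names(age_bands), "other")
  count_labels <- c(as.character(0:(max_drug_count - 1L)),
                    paste0(max_drug_count, "+"))

  assign_one <- function(p) {
    fl <- comorbidity_flags(p$icd9_codes, code_policy)
    k <- count_drugs_of_interest(p$medications, formulary, policy, patterns)
    data.frame(patient_id = p$patient_id,
               age_band = age_band_label(p$age, age_bands),
               drug_count = drug_count_label(k, max_drug_count),
               htn = unname(fl["htn"]), dm = unname(fl["dm"]),
               appointment_date = p$appointment_date,
               stringsAsFactors = FALSE)
  }
  assignments <- if (length(in_win)) {
    do.call(rbind, lapply(in_win, assign_one))
  } else {
    data.frame(patient_id = character(0), age_band = character(0),
               drug_count = character(0), htn = logical(0), dm = logical(0),
               appointment_date = as.Date(character(0)),
               stringsAsFactors = FALSE)
  }

  cells <- expand.grid(drug_count = count_labels, age_band = band_labels,
                       stringsAsFactors = FALSE)[, c("age_band", "drug_count")]
  tally <- function(band, count) {
    rows <- assignments[assignments$age_band == band &
                          assignments$drug_count == count, , drop = FALSE]
    c(n_total = nrow(rows),
      n_htn_only = sum(rows$htn & !rows$dm),
      n_dm_only = sum(rows$dm & !rows$htn),
      n_both = sum(rows$htn & rows$dm))
  }
  counts <- t(mapply(tally, cells$age_band, cells$drug_count))
  cells <- cbind(cells, as.data.frame(counts, row.names = NULL))

  patients <- stats::setNames(in_win,
                              vapply(in_win, function(p) p$patient_id,
                                     character(1)))
  structure(list(window = window, age_bands = age_bands,
                 drug_counts = count_labels, cells = cells,
                 assignments = assignments, patients = patients),
            class = "screening_grid")
}

#' @export
print.screening_grid <- function(x, ...) {
  cat(sprintf("<screening_grid> window [%s, %s), %d patient(s)\n",
              format(x$window[1]), format(x$window[2]), length(x$patients)))
  nz <- x$cells[x$cells$n_total > 0, , drop = FALSE]
  if (nrow(nz)) {
    nz$note <- sprintf("H%d D%d B%d", nz$n_htn_only, nz$n_dm_only, nz$n_both)
    print(nz[, c("age_band", "drug_count", "n_total", "note")],
          row.names = FALSE)
  } else {
    cat("  (all cells empty)\n")
  }
  invisible(x)
}

#' List the patients in selected grid cells
#'
#' The recruitment follow-up to the grid: the union of patients in the
#' selected cells, with contact details, sorted by appointment date then
#' patient id.
#'
#' @param grid a [build_screening_grid()] result.
#' @param selected_cells data frame with columns `age_band` and `drug_count`
#'   naming existing cells.
#' @return list of `patient_snapshot` references (possibly empty).
#' @export
list_patients_in_cells <- function(grid, selected_cells) {
  stopifnot(inherits(grid, "screening_grid"),
            all(c("age_band", "drug_count") %in% names(selected_cells)))
  key <- function(b, k) paste(b, k, sep = "\r")
  valid <- key(grid$cells$age_band, grid$cells$drug_count)
  want <- key(selected_cells$age_band, selected_cells$drug_count)
  if (!all(want %in% valid)) {
    stop("selected cell(s) not present in the grid")
  }
  a <- grid$assignments
  rows <- a[key(a$age_band, a$drug_count) %in% want, , drop = FALSE]
  rows <- rows[order(rows$appointment_date, rows$patient_id), , drop = FALSE]
  unname(grid$patients[rows$patient_id])
}
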