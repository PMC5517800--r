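#' Specify a synthetic fixture generator run
#'
#' The generator emulates the messy free-text dialect of EHR medication
#' entries — doses embedded in either field, decorated names, as-directed and
#' as-needed instructions, weekday schedules, conflicting doses — with
#' complete per-entry ground truth, so the parsing, classification and
#' screening pipeline can be tested end to end without any real patient
#' data. Identical specs produce byte-identical output.
#'
#' @param seed integer RNG seed.
#' @param n number of entries (or patients) to generate.
#' @param anomaly_rate fraction in `[0, 1]` of entries corrupted so that no
#'   grammar pattern matches; ground truth marks them unparseable.
#' @param dialect_mix named non-negative weights, summing to 1, over the
#'   entry archetypes `clean_name_dose` (dose in the name field, schedule
#'   phrase in the sig), `sig_dose` (dose and schedule both in the sig),
#'   `decorated` (name carrying synonym/indication/inline-schedule
#'   decorations), `as_directed`, `prn`, `weekly` and `conflict` (different
#'   doses in name and sig).
#' @param cohort_params list for [generate_patient_cohort()]: `age_range`
#'   (inclusive integer bounds), `prev_htn` and `prev_dm` (condition
#'   prevalences), `drugs_lambda` (Poisson mean of drugs per patient above
#'   one), and `window` (length-2 `Date`; appointments are drawn from a few
#'   days before the start to a few days after the end so that window
#'   filtering is exercised).
#' @return a list of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n = 100L, anomaly_rate = 0,
                           dialect_mix = c(clean_name_dose = 0.30,
                                           sig_dose = 0.20,
                                           decorated = 0.15,
                                           as_directed = 0.10,
                                           prn = 0.10,
                                           weekly = 0.10,
                                           conflict = 0.05),
                           cohort_params = list(
                             age_range = c(65, 94),
                             prev_htn = 0.6,
                             prev_dm = 0.35,
                             drugs_lambda = 6,
                             window = as.Date(c("2015-11-11", "2015-11-25")))) {
  stopifnot(anomaly_rate >= 0, anomaly_rate <= 1,
            abs(sum(dialect_mix) - 1) < 1e-8, all(dialect_mix >= 0),
            n >= 0)
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 anomaly_rate = anomaly_rate, dialect_mix = dialect_mix,
                 cohort_params = cohort_params),
            class = "generator_spec")
}

SCHEDULE_PHRASE_POOL <- data.frame(
  phrase = c("AT BEDTIME", "ONCE DAILY", "TWICE DAILY",
             "THREE TIMES A DAY", "FOUR TIMES A DAY"),
  code = c("QHS", "QD", "BID", "TID", "QID"),
  per_day = c(1L, 1L, 2L, 3L, 4L),
  stringsAsFactors = FALSE)

DOSE_POOL <- c(5, 10, 20, 25, 40, 50, 75, 81, 100, 150, 162, 300, 325, 500)

truth_row <- function(base_name, dose_value = NA_real_,
                      dose_unit = NA_character_, schedule_code = "UNKNOWN",
                      per_day = NA_integer_, per_week = NA_integer_,
                      quantity = 1L, daily_dose = NA_real_,
                      category = NA_character_, parseable = TRUE) {
  data.frame(base_name = base_name, dose_value = dose_value,
             dose_unit = dose_unit, schedule_code = schedule_code,
             per_day = per_day, per_week = per_week, quantity = quantity,
             daily_dose = daily_dose, category = category,
             parseable = parseable, stringsAsFactors = FALSE)
}

# category a drug would receive under the default policy, straight from the
# formulary row (generator-side knowledge, independent of classify_medication)
truth_category <- function(frow, policy) {
  if (isTRUE(frow$is_supply)) return("SUPPLY")
  if (toupper(frow$drug_class) %in% policy$excluded_classes) return("EXCLUDED")
  "OF_INTEREST"
}

# One synthetic entry of a given archetype for a given formulary row.
make_entry <- function(archetype, frow, policy) {
  nm <- frow$canonical_name
  unit <- sample(c("MG", "MG", "MG", "MCG", "MEQ"), 1L)
  dose <- sample(DOSE_POOL, 1L)
  sched <- SCHEDULE_PHRASE_POOL[sample(nrow(SCHEDULE_PHRASE_POOL), 1L), ]
  form <- sample(c("TAB", "CAP"), 1L)
  qty <- sample(c(1L, 1L, 1L, 2L), 1L)
  qty_word <- c("ONE", "TWO")[qty]
  admin <- if (form == "CAP") "CAPSULE" else "TABLET"
  if (qty > 1L) admin <- paste0(admin, "S")
  cat <- truth_category(frow, policy)

  if (archetype == "clean_name_dose") {
    entry <- raw_medication_entry(
      sprintf("%s %g %s, %s", nm, dose, unit, form),
      sprintf("TAKE %s %s BY MOUTH %s", qty_word, admin, sched$phrase))
    tr <- truth_row(nm, dose, unit, sched$code, sched$per_day,
                    quantity = qty, daily_dose = dose * qty * sched$per_day,
                    category = cat)
  } else if (archetype == "sig_dose") {
    entry <- raw_medication_entry(
      sprintf("%s %s", nm, form),
      sprintf("%g%s MOUTH %s", dose, unit, sched$phrase))
    tr <- truth_row(nm, dose, unit, sched$code, sched$per_day,
                    daily_dose = dose * sched$per_day, category = cat)
  } else if (archetype == "decorated") {
    deco <- sample(c("synonym", "indication", "inline"), 1L)
    decorated <- switch(deco,
      synonym = sprintf("%s(BRAND%d)", nm, sample(99L, 1L)),
      indication = sprintf("%s<PAIN>", nm),
      inline = {
        toks <- name_tokens(nm)
        paste0(toks[1L], sprintf("*%s*", sched$phrase),
               paste(toks[-1L], collapse = " "))
      })
    entry <- raw_medication_entry(
      sprintf("%s %g %s %s", decorated, dose, unit, form),
      sprintf("TAKE %s %s BY MOUTH %s", qty_word, admin, sched$phrase))
    tr <- truth_row(nm, dose, unit, sched$code, sched$per_day,
                    quantity = qty, daily_dose = dose * qty * sched$per_day,
                    category = cat)
  } else if (archetype == "as_directed") {
    entry <- raw_medication_entry(
      sprintf("%s %g%s %s", nm, dose, unit, form),
      "TAKE AS DIRECTED BY MOUTH AS INSTRUCTED BY CLINIC")
    tr <- truth_row(nm, dose, unit, "AS_DIRECTED", category = cat)
  } else if (archetype == "prn") {
    entry <- raw_medication_entry(
      sprintf("%s %g%s %s", nm, dose, unit, form),
      sprintf("TAKE %s %s BY MOUTH AS NEEDED", qty_word, admin))
    tr <- truth_row(nm, dose, unit, "PRN", quantity = qty, category = cat)
  } else if (archetype == "weekly") {
    ndays <- sample(1:3, 1L)
    days <- sort(sample(7L, ndays))
    daynames <- default_patterns()$weekday_names[days]
    daytext <- if (ndays == 1L) daynames
    else paste(paste(daynames[-ndays], collapse = ", "), "AND",
               daynames[ndays])
    entry <- raw_medication_entry(
      sprintf("%s %s", nm, form),
      sprintf("%g%s MOUTH %s", dose, unit, daytext))
    tr <- truth_row(nm, dose, unit, "WEEKLY_DAYS", per_week = ndays,
                    category = cat)
  } else if (archetype == "conflict") {
    entry <- raw_medication_entry(
      sprintf("%s(%g %s) %s, EC", nm, dose, unit, form),
      sprintf("%g%s MOUTH", dose * 2, unit))
    tr <- truth_row(nm, dose * 2, unit, "UNKNOWN", category = cat)
  } else {
    stop("unknown archetype: ", archetype)
  }
  list(entry = entry, truth = cbind(tr, archetype = archetype,
                                    stringsAsFactors = FALSE))
}

# Corrupt an entry so neither the dose nor the schedule grammar can match.
corrupt_entry <- function(frow) {
  junk <- sample(c("USE AS SHOWN ON PACKAGE INSERT", "SEE NOTES",
                   "PER PHARMACY PROTOCOL", ""), 1L)
  entry <- raw_medication_entry(sprintf("%s MISC", frow$canonical_name), junk)
  list(entry = entry,
       truth = cbind(truth_row(frow$canonical_name, parseable = FALSE,
                               category = NA_character_),
                     archetype = "anomaly", stringsAsFactors = FALSE))
}

#' Generate ground-truthed synthetic medication entries
#'
#' Draws `spec$n` entries from the archetype mix over the non-supply drugs of
#' `formulary`; an `anomaly_rate` fraction is corrupted so that neither the
#' dose nor the schedule grammar matches, and ground truth marks those rows
#' unparseable. Deterministic under `spec$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param spec a [generator_spec()].
#' @param formulary a formulary data frame; non-supply rows are sampled.
#' @param policy the [classification_policy()] used to record each entry's
#'   ground-truth category.
#' @return list with `entries` (list of [raw_medication_entry()]) and `truth`
#'   (data frame, one row per entry: `base_name`, `dose_value`, `dose_unit`,
#'   `schedule_code`, `per_day`, `per_week`, `quantity`, `daily_dose`,
#'   `category`, `parseable`, `archetype`).
#' @export
generate_medication_entries <- function(spec, formulary = example_formulary(),
                                        policy = classification_policy()) {
  stopifnot(inherits(spec, "generator_spec"), nrow(formulary) > 0L)
  drugs <- formulary[!formulary$is_supply, , drop = FALSE]
  stopifnot(nrow(drugs) > 0L)
  with_preserved_seed(spec$seed, {
    entries <- vector("list", spec$n)
    truths <- vector("list", spec$n)
    if (spec$n > 0L) {
      archetypes <- sample(names(spec$dialect_mix), spec$n, replace = TRUE,
                           prob = spec$dialect_mix)
      anomalous <- runif(spec$n) < spec$anomaly_rate
      rows <- sample(nrow(drugs), spec$n, replace = TRUE)
      for (i in seq_len(spec$n)) {
        frow <- drugs[rows[i], , drop = FALSE]
        out <- if (anomalous[i]) corrupt_entry(frow)
               else make_entry(archetypes[i], frow, policy)
        entries[[i]] <- out$entry
        truths[[i]] <- out$truth
      }
    }
    list(entries = entries,
         truth = if (spec$n > 0L) do.call(rbind, truths)
                 else cbind(truth_row(""), archetype = "",
                            stringsAsFactors = FALSE)[0L, ])
  })
}

NOISE_ICD9 <- c("272.4", "530.81", "715.90", "414.01", "V58.69", "496")
HTN_ICD9 <- c("401.1", "401.9", "402.90", "403.90")
DM_ICD9 <- c("250.00", "250.02", "250.60")

#' Generate a ground-truthed synthetic patient cohort
#'
#' Each patient gets an age drawn uniformly from `age_range`, hypertension
#' and diabetes status drawn at the configured prevalences (realized as
#' ICD-9 codes, alongside unrelated noise codes), an appointment date drawn
#' from the screening window widened by five days on each side (so some
#' patients fall outside the window), and a medication list mixing
#' of-interest, excluded-class and supply entries built from the formulary.
#' Ground truth records each patient's true flags, in-window status and
#' distinct drugs-of-interest count.
#'
#' @inheritParams generate_medication_entries
#' @return list with `patients` (list of [patient_snapshot()]) and `truth`
#'   (data frame: `patient_id`, `age`, `htn`, `dm`, `n_of_interest`,
#'   `appointment_date`, `in_window`).
#' @export
generate_patient_cohort <- function(spec, formulary = example_formulary(),
                                    policy = classification_policy()) {
  stopifnot(inherits(spec, "generator_spec"))
  cp <- spec$cohort_params
  window <- as.Date(cp$window)
  drugs <- formulary[!formulary$is_supply, , drop = FALSE]
  supplies <- formulary[formulary$is_supply, , drop = FALSE]

  with_preserved_seed(spec$seed + 104729L, {  # offset: independent of entries
    patients <- vector("list", spec$n)
    truths <- vector("list", spec$n)
    days <- seq(window[1] - 5L, window[2] + 5L, by = "day")
    for (i in seq_len(spec$n)) {
      id <- sprintf("P%04d", i)
      age <- sample(cp$age_range[1]:cp$age_range[2], 1L)
      htn <- runif(1) < cp$prev_htn
      dm <- runif(1) < cp$prev_dm
      codes <- c(if (htn) sample(HTN_ICD9, 1L),
                 if (dm) sample(DM_ICD9, 1L),
                 sample(NOISE_ICD9, sample(0:3, 1L)))
      appt <- sample(days, 1L)

      n_drugs <- 1L + rpois(1L, cp$drugs_lambda)
      rows <- sample(nrow(drugs), min(n_drugs, nrow(drugs)))
      meds <- list()
      n_interest <- 0L
      for (r in rows) {
        frow <- drugs[r, , drop = FALSE]
        out <- make_entry(sample(c("clean_name_dose", "sig_dose", "prn"), 1L,
                                 prob = c(0.6, 0.3, 0.1)),
                          frow, policy)
        meds <- c(meds, list(out$entry))
        if (out$truth$category == "OF_INTEREST") n_interest <- n_interest + 1L
      }
      if (runif(1) < 0.3 && nrow(supplies)) {
        srow <- supplies[sample(nrow(supplies), 1L), , drop = FALSE]
        meds <- c(meds, list(raw_medication_entry(srow$canonical_name)))
      }

      patients[[i]] <- patient_snapshot(
        patient_id = id, age = age, icd9_codes = codes,
        appointment_date = appt, clinic_name = "PRIMARY CARE",
        medications = meds, contact = sprintf("patient %s, tel 555-%04d", id, i))
      truths[[i]] <- data.frame(
        patient_id = id, age = age, htn = htn, dm = dm,
        n_of_interest = n_interest, appointment_date = appt,
        in_window = appt >= window[1] && appt < window[2],
        stringsAsFactors = FALSE)
    }
    list(patients = patients,
         truth = if (spec$n > 0L) do.call(rbind, truths)
                 else data.frame(patient_id = character(0)))
  })
}

#' Write the fixture files a generator run produces
#'
#' Emits the file formats consumed by the other modules: `meds.csv`
#' (columns `name_text`, `sig_text`, `source`, `dose_text`),
#' `meds_truth.csv` (the ground-truth sidecar), `cohort.jsonl` (one patient
#' snapshot per line, medications nested) and `cohort_truth.csv`.
#'
#' @param spec a [generator_spec()].
#' @param out_dir output directory (created if needed).
#' @param formulary,policy as in [generate_medication_entries()].
#' @return the output directory, invisibly.
#' @export
write_fixtures <- function(spec, out_dir, formulary = example_formulary(),
                           policy = classification_policy()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  med <- generate_medication_entries(spec, formulary, policy)
  meds_df <- do.call(rbind, lapply(med$entries, function(e) {
    data.frame(name_text = e$name_text, sig_text = e$sig_text,
               source = e$source, dose_text = e$dose_text,
               stringsAsFactors = FALSE)
  }))
  write.csv(meds_df, file.path(out_dir, "meds.csv"), row.names = FALSE)
  write.csv(med$truth, file.path(out_dir, "meds_truth.csv"), row.names = FALSE)

  coh <- generate_patient_cohort(spec, formulary, policy)
  lines <- vapply(coh$patients, function(p) {
    jsonlite::toJSON(list(
      patient_id = p$patient_id, age = p$age,
      icd9_codes = as.list(p$icd9_codes),
      appointment_date = format(p$appointment_date),
      clinic_name = p$clinic_name,
      medications = lapply(p$medications, function(e) {
        list(name_text = e$name_text, sig_text = e$sig_text,
             source = e$source, dose_text = e$dose_text)
      }),
      contact = p$contact), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, file.path(out_dir, "cohort.jsonl"))
  write.csv(coh$truth, file.path(out_dir, "cohort_truth.csv"),
            row.names = FALSE)
  invisible(out_dir)
}
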