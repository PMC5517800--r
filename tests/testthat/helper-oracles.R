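# Independent reference implementations used as oracles. These deliberately
# avoid the package's regex path: the dose matcher below interprets the
# dose grammar literally by enumerating decompositions, character by
# character.

# All complete matches of the dose grammar starting at position i:
#   optional "(", a decimal number (digits+ or digits* "." digits+),
#   whitespace*, a unit (mg|mcg|meq case-insensitive), optional ")".
# Returns the largest end position (1-based inclusive), or NA.
ref_match_at <- function(ch, i) {
  n <- length(ch)
  is_digit <- function(c) c >= "0" && c <= "9"
  best <- NA_integer_
  note <- function(end) if (is.na(best) || end > best) best <<- end

  try_from_number <- function(p) {
    # enumerate every valid number parse starting at p
    ends <- integer(0)
    da <- 0L
    while (p + da <= n && is_digit(ch[p + da])) da <- da + 1L
    if (da > 0L) ends <- c(ends, p + seq_len(da) - 1L)        # digits+
    for (k in 0:da) {                                          # digits* . digits+
      dot <- p + k
      if (dot > n || ch[dot] != ".") next
      db <- 0L
      while (dot + 1L + db <= n && is_digit(ch[dot + 1L + db])) db <- db + 1L
      if (db > 0L) ends <- c(ends, dot + seq_len(db))
    }
    for (q in unique(ends)) try_from_ws(q + 1L, q)
  }
  try_from_ws <- function(p, num_end) {
    w <- p
    repeat {
      try_unit(w)
      if (w <= n && grepl("^\\s$", ch[w])) w <- w + 1L else break
    }
  }
  try_unit <- function(p) {
    for (u in c("mg", "mcg", "meq")) {
      len <- nchar(u)
      if (p + len - 1L > n) next
      if (tolower(paste(ch[p:(p + len - 1L)], collapse = "")) == u) {
        end <- p + len - 1L
        note(end)
        if (end + 1L <= n && ch[end + 1L] == ")") note(end + 1L)
      }
    }
  }

  if (i <= n && ch[i] == "(") try_from_number(i + 1L)
  try_from_number(i)
  best
}

# Non-overlapping left-to-right scan with the reference matcher; returns a
# data frame shaped like extract_dose()'s result.
ref_dose_matches <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  out <- data.frame(value = numeric(0), unit = character(0),
                    start = integer(0), end = integer(0),
                    match = character(0), stringsAsFactors = FALSE)
  i <- 1L
  while (i <= n) {
    end <- ref_match_at(ch, i)
    if (is.na(end)) {
      i <- i + 1L
    } else {
      sub <- substring(s, i, end)
      core <- gsub("[()]", "", sub)
      unit <- toupper(sub(".*?((?i)mg|mcg|meq)\\s*$", "\\1", core, perl = TRUE))
      value <- as.numeric(sub("(?i)(mg|mcg|meq)\\s*$", "", core, perl = TRUE))
      out <- rbind(out, data.frame(value = value, unit = unit,
                                   start = i, end = end, match = sub,
                                   stringsAsFactors = FALSE))
      i <- end + 1L
    }
  }
  out
}

# Brute-force per-patient tally of a screening grid: classify each in-window
# patient independently and count with table(), no shared grid code.
brute_force_grid_tally <- function(cohort, window, age_bands, formulary,
                                   policy, max_drug_count = 10L) {
  rows <- list()
  seen <- character(0)
  ord <- order(vapply(cohort, function(p) as.numeric(p$appointment_date),
                      numeric(1)),
               vapply(cohort, function(p) p$patient_id, character(1)))
  for (p in cohort[ord]) {
    if (p$appointment_date < window[1] || p$appointment_date >= window[2]) next
    if (p$patient_id %in% seen) next
    seen <- c(seen, p$patient_id)
    band <- "other"
    for (lab in names(age_bands)) {
      b <- age_bands[[lab]]
      if (p$age >= b[1] && p$age <= b[2]) { band <- lab; break }
    }
    k <- count_drugs_of_interest(p$medications, formulary, policy)
    kl <- if (k >= max_drug_count) paste0(max_drug_count, "+") else as.character(k)
    fl <- comorbidity_flags(p$icd9_codes)
    rows[[length(rows) + 1L]] <- data.frame(
      age_band = band, drug_count = kl,
      htn = unname(fl["htn"]), dm = unname(fl["dm"]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# End-to-end ground-truth recovery check for one generated entry.
entry_recovers_truth <- function(entry, truth, formulary, policy) {
  p <- parse_entry(entry)
  cl <- classify_medication(p, formulary, policy)
  dv <- if (is.null(p$dose)) NA_real_ else p$dose$value
  du <- if (is.null(p$dose)) NA_character_ else p$dose$unit
  dd <- if (is.null(p$total_daily_dose)) NA_real_ else p$total_daily_dose$value
  pw <- p$schedule$per_week
  identical(p$schedule$code, truth$schedule_code) &&
    (is.na(truth$dose_value) && is.na(dv) ||
       isTRUE(all.equal(dv, truth$dose_value))) &&
    identical(du, truth$dose_unit) &&
    (is.na(truth$daily_dose) && is.na(dd) ||
       isTRUE(all.equal(dd, truth$daily_dose))) &&
    (is.na(truth$per_week) && is.na(pw) || identical(pw, truth$per_week)) &&
    identical(cl$base_name, truth$base_name) &&
    identical(cl$category, truth$category)
}

# An entry the parser could make nothing of: no dose anywhere, no schedule.
flagged_unparseable <- function(parsed) {
  is.null(parsed$dose) && parsed$schedule$code == "UNKNOWN"
}

random_alphabet_strings <- function(n, alphabet, max_len) {
  vapply(seq_len(n), function(i) {
    len <- sample(max_len, 1L)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}
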