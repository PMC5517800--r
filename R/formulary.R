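#' Normalize a decorated drug name
#'
#' EHR Drug Name fields are free text and accumulate decorations around the
#' actual drug name: embedded doses (`"PROPRANOLOL 10 MG"`), dose-form
#' suffixes (`TAB`, `CAP`, `TAB,SA`, `TAB,EC`), bracketed tags (`"[OTC]"`),
#' parenthesized brand synonyms (`"(LAMICTAL)"`), asterisk-delimited schedule
#' inserts (`"*TWICE DAILY*"`) and angle-bracketed indications
#' (`"<SEIZURES>"`). This function uppercases the name, strips each
#' decoration into a tag, and returns the residual base name with whitespace
#' (and stray punctuation) collapsed. It is idempotent.
#'
#' @param name_text non-empty drug name free text.
#' @param patterns a pattern registry ([default_patterns()]), used for dose
#'   spans and form suffixes.
#' @return a list with `base_name` (uppercase; `""` when nothing but
#'   decorations remained) and `tags`, a named list where `SYNONYM`,
#'   `INLINE_SCHEDULE` and `INDICATION` carry their extracted text and any
#'   bracketed tag (e.g. `OTC`) carries `TRUE`.
#' @examples
#' normalize_name("NIACIN(SLO-NIACIN) [OTC] TAB, SA")
#' normalize_name("METOPROLOL*TWICE DAILY*TARTRATE TAB")
#' @export
normalize_name <- function(name_text, patterns = default_patterns()) {
  stopifnot(is.character(name_text), length(name_text) == 1L, !is.na(name_text))
  x <- toupper(trimws(name_text))
  tags <- list()

  blank_span <- function(s, start, end) {
    paste0(substring(s, 1L, start - 1L),
           strrep(" ", end - start + 1L),
           substring(s, end + 1L))
  }
  doses <- extract_dose(x, patterns)
  if (nrow(doses)) {
    for (i in seq_len(nrow(doses))) x <- blank_span(x, doses$start[i], doses$end[i])
  }

  grab <- function(rx, tag) {
    m <- regmatches(x, gregexpr(rx, x, perl = TRUE))[[1]]
    if (length(m)) {
      val <- trimws(gsub("^[][*()<>]+|[][*()<>]+$", "", m))
      val <- val[nzchar(val)]
      if (length(val)) {
        if (is.na(tag)) {
          for (v in val) tags[[v]] <<- TRUE
        } else if (is.null(tags[[tag]])) {
          tags[[tag]] <<- val[1L]
        }
      }
      x <<- gsub(rx, " ", x, perl = TRUE)
    }
  }
  grab("\\*[^*]*\\*", "INLINE_SCHEDULE")
  grab("\\[[^]\\[]*\\]", NA)          # bracket content becomes a flag tag
  grab("<[^<>]*>", "INDICATION")
  grab("\\([^()]*\\)", "SYNONYM")

  # strip trailing dose-form tokens, then collapse separators
  tokens <- strsplit(gsub("[,.]+", " ", x), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  while (length(tokens) && tokens[length(tokens)] %in% patterns$form_suffixes) {
    tokens <- tokens[-length(tokens)]
  }
  list(base_name = paste(tokens, collapse = " "), tags = tags)
}

#' Read a formulary table
#'
#' A formulary is a data frame with columns `canonical_name` (uppercase,
#' unique), `drug_class` (non-empty for non-supply rows) and `is_supply`
#' (logical). Drug classes are the lookup key for the exclusion policy in
#' [classify_medication()].
#'
#' @param path CSV file with those three columns.
#' @return the validated formulary data frame.
#' @export
read_formulary <- function(path) {
  f <- read.csv(path, stringsAsFactors = FALSE)
  as_formulary(f)
}

as_formulary <- function(f) {
  stopifnot(all(c("canonical_name", "drug_class", "is_supply") %in% names(f)))
  f$canonical_name <- toupper(trimws(f$canonical_name))
  f$is_supply <- as.logical(f$is_supply)
  if (anyDuplicated(f$canonical_name)) {
    stop("duplicate canonical_name in formulary")
  }
  if (any(!f$is_supply & !nzchar(f$drug_class))) {
    stop("non-supply formulary rows must carry a drug_class")
  }
  f
}

#' A small built-in example formulary
#'
#' Thirty-odd entries spanning cardiovascular, CNS, endocrine and other
#' classes plus vitamins, topicals, ophthalmics, cough/cold products,
#' antibiotics and non-drug supplies, sufficient to exercise classification
#' and the synthetic generators. Real deployments supply their own table via
#' [read_formulary()].
#'
#' @return a formulary data frame.
#' @export
example_formulary <- function() {
  e <- function(name, class, supply = FALSE) {
    data.frame(canonical_name = name, drug_class = class, is_supply = supply,
               stringsAsFactors = FALSE)
  }
  as_formulary(rbind(
    e("PROPRANOLOL", "BETA_BLOCKER"),
    e("METOPROLOL TARTRATE", "BETA_BLOCKER"),
    e("METOPROLOL SUCCINATE", "BETA_BLOCKER"),
    e("LISINOPRIL", "ACE_INHIBITOR"),
    e("AMLODIPINE", "CALCIUM_BLOCKER"),
    e("FUROSEMIDE", "LOOP_DIURETIC"),
    e("HYDROCHLOROTHIAZIDE", "THIAZIDE"),
    e("WARFARIN NA", "ANTICOAGULANT"),
    e("ASPIRIN", "ANTIPLATELET"),
    e("GABAPENTIN", "ANTICONVULSANT"),
    e("LAMOTRIGINE", "ANTICONVULSANT"),
    e("AMITRIPTYLINE", "TRICYCLIC_ANTIDEPRESSANT"),
    e("NORTRIPTYLINE", "TRICYCLIC_ANTIDEPRESSANT"),
    e("DULOXETINE", "SNRI_ANTIDEPRESSANT"),
    e("SERTRALINE", "SSRI_ANTIDEPRESSANT"),
    e("SUMATRIPTAN SUCCINATE", "ANTIMIGRAINE"),
    e("METFORMIN", "ORAL_HYPOGLYCEMIC"),
    e("GLIPIZIDE", "ORAL_HYPOGLYCEMIC"),
    e("INSULIN GLARGINE", "INSULIN"),
    e("LEVOTHYROXINE", "THYROID_HORMONE"),
    e("SIMVASTATIN", "STATIN"),
    e("ATORVASTATIN", "STATIN"),
    e("OMEPRAZOLE", "PROTON_PUMP_INHIBITOR"),
    e("NIACIN", "ANTILIPEMIC"),
    e("TRAMADOL", "OPIOID_ANALGESIC"),
    e("MULTIVITAMIN", "VITAMINS"),
    e("CYANOCOBALAMIN", "VITAMINS"),
    e("GUAIFENESIN", "COUGH_COLD"),
    e("DEXTROMETHORPHAN", "COUGH_COLD"),
    e("HYDROCORTISONE CREAM", "DERM_TOPICAL"),
    e("ARTIFICIAL TEARS", "OPHTHALMIC"),
    e("LATANOPROST", "OPHTHALMIC"),
    e("AMOXICILLIN", "ANTIBIOTIC"),
    e("DOXYCYCLINE", "ANTIBIOTIC"),
    e("LANCETS, BLOOD GLUCOSE", "SUPPLY", TRUE),
    e("SYRINGE, INSULIN", "SUPPLY", TRUE),
    e("INHALER SPACER", "SUPPLY", TRUE),
    e("ADULT DIAPERS", "SUPPLY", TRUE)
  ))
}

name_tokens <- function(x) {
  t <- strsplit(gsub("[^A-Z0-9]+", " ", toupper(x)), "\\s+")[[1]]
  t[nzchar(t)]
}

#' Match a normalized base name against a formulary
#'
#' `EXACT` when the base name equals a canonical name; otherwise
#' `NORMALIZED` when exactly one canonical name is a token-prefix of the base
#' name or vice versa (so `"ASPIRIN ENTERIC COATED"` finds `ASPIRIN`); ties
#' between multiple candidate drugs resolve to `UNMATCHED` — for a screening
#' application a missed match is safer than a guessed one.
#'
#' @param base_name output of [normalize_name()]`$base_name`.
#' @param formulary a formulary data frame.
#' @return list with `entry` (one-row data frame or `NULL`) and
#'   `match_quality` (`"EXACT"`, `"NORMALIZED"` or `"UNMATCHED"`).
#' @export
match_formulary <- function(base_name, formulary) {
  stopifnot(nrow(formulary) > 0L)
  base_name <- toupper(trimws(base_name))
  if (!nzchar(base_name)) {
    return(list(entry = NULL, match_quality = "UNMATCHED"))
  }
  hit <- which(formulary$canonical_name == base_name)
  if (length(hit) == 1L) {
    return(list(entry = formulary[hit, , drop = FALSE],
                match_quality = "EXACT"))
  }
  bt <- name_tokens(base_name)
  is_prefix <- function(a, b) {
    length(a) <= length(b) && all(a == b[seq_along(a)])
  }
  cand <- which(vapply(formulary$canonical_name, function(cn) {
    ct <- name_tokens(cn)
    is_prefix(ct, bt) || is_prefix(bt, ct)
  }, logical(1)))
  if (length(cand) == 1L) {
    return(list(entry = formulary[cand, , drop = FALSE],
                match_quality = "NORMALIZED"))
  }
  list(entry = NULL, match_quality = "UNMATCHED")
}

#' Classification policy
#'
#' Pure configuration for [classify_medication()]: which drug classes are
#' excluded from the polypharmacy count (vitamins, cough/cold remedies, OTC
#' items, skin creams, ophthalmic agents), which keywords identify non-drug
#' supplies that the EHR stores alongside medications (lancets, syringes,
#' inhaler spacers, diapers, ...), and how short-term antibiotic courses are
#' handled: an antibiotic-class drug is excluded only when a days-supply
#' value is provided and does not exceed `antibiotic_days_threshold`;
#' otherwise it is retained as a drug of interest, since class membership
#' alone cannot distinguish a short course from chronic suppression.
#'
#' @param excluded_classes drug_class codes excluded from the
#'   drugs-of-interest count.
#' @param supply_keywords tokens whose presence in a drug name marks a
#'   non-drug supply.
#' @param antibiotic_classes drug_class codes subject to the days-supply
#'   rule.
#' @param antibiotic_days_threshold maximum days supply (inclusive) for an
#'   antibiotic course to count as short-term, default 30.
#' @return a list of class `classification_policy`.
#' @export
classification_policy <- function(
    excluded_classes = c("VITAMINS", "COUGH_COLD", "OTC_MISC",
                         "DERM_TOPICAL", "OPHTHALMIC"),
    supply_keywords = c("LANCET", "LANCETS", "SYRINGE", "SYRINGES", "SPACER",
                        "DIAPER", "DIAPERS", "NEEDLE", "NEEDLES", "GAUZE",
                        "TEST STRIP", "TEST STRIPS"),
    antibiotic_classes = "ANTIBIOTIC",
    antibiotic_days_threshold = 30) {
  structure(list(excluded_classes = toupper(excluded_classes),
                 supply_keywords = toupper(supply_keywords),
                 antibiotic_classes = toupper(antibiotic_classes),
                 antibiotic_days_threshold = antibiotic_days_threshold),
            class = "classification_policy")
}

#' Read a classification policy from YAML or JSON
#' @param path config file; keys as in [classification_policy()].
#' @return a `classification_policy`.
#' @export
read_policy <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(classification_policy,
          raw[intersect(names(raw), names(formals(classification_policy)))])
}

#' Classify a parsed medication against a formulary and policy
#'
#' Partitions every medication into exactly one category:
#' `SUPPLY` when a supply keyword hits the raw name or the matched formulary
#' row is flagged as a supply; else `EXCLUDED` when the matched drug class is
#' in the policy's excluded set, the name carried an `[OTC]` tag, or the
#' short-term-antibiotic rule applies; else `OF_INTEREST` when a formulary
#' match exists; else `UNMATCHED`.
#'
#' @param parsed a [parse_entry()] result.
#' @param formulary a formulary data frame.
#' @param policy a [classification_policy()].
#' @param days_supply optional days-supply for the antibiotic rule.
#' @inheritParams extract_dose
#' @return an object of class `classified_medication`: list with `parsed`,
#'   `base_name`, `tags`, `matched` (formulary row or `NULL`),
#'   `match_quality` and `category`.
#' @export
classify_medication <- function(parsed, formulary,
                                policy = classification_policy(),
                                days_supply = NA_real_,
                                patterns = default_patterns()) {
  stopifnot(inherits(parsed, "parsed_medication"),
            inherits(policy, "classification_policy"))
  norm <- normalize_name(parsed$raw$name_text, patterns)
  m <- match_formulary(norm$base_name, formulary)

  upname <- toupper(parsed$raw$name_text)
  keyword_hit <- any(vapply(policy$supply_keywords, function(k) {
    grepl(paste0("\\b", k, "\\b"), upname, perl = TRUE)
  }, logical(1)))

  category <- if (keyword_hit || (!is.null(m$entry) && m$entry$is_supply)) {
    "SUPPLY"
  } else {
    cls <- if (!is.null(m$entry)) toupper(m$entry$drug_class) else NA_character_
    short_abx <- !is.na(cls) && cls %in% policy$antibiotic_classes &&
      !is.na(days_supply) && days_supply <= policy$antibiotic_days_threshold
    if (isTRUE(tags_has(norm$tags, "OTC")) ||
        (!is.na(cls) && cls %in% policy$excluded_classes) || short_abx) {
      "EXCLUDED"
    } else if (!is.null(m$entry)) {
      "OF_INTEREST"
    } else {
      "UNMATCHED"
    }
  }

  structure(list(parsed = parsed, base_name = norm$base_name,
                 tags = norm$tags, matched = m$entry,
                 match_quality = m$match_quality, category = category),
            class = "classified_medication")
}

tags_has <- function(tags, tag) !is.null(tags[[tag]])
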