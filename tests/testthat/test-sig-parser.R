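test_that("dose extraction handles the canonical dose spellings", {
  cases <- list(
    list("GABAPENTIN 300 MG, CAP", 300, "MG"),
    list("32.5 MG", 32.5, "MG"),
    list("18MCG", 18, "MCG"),
    list("(1.5 meq)", 1.5, "MEQ"),
    list("ASPIRIN, ENTERIC COATED(81 MG) TAB, EC", 81, "MG")
  )
  for (cs in cases) {
    d <- extract_dose(cs[[1]])
    expect_equal(nrow(d), 1L, info = cs[[1]])
    expect_equal(d$value, cs[[2]], info = cs[[1]])
    expect_equal(d$unit, cs[[3]], info = cs[[1]])
    # the covered substring re-parses to the same (value, unit)
    again <- extract_dose(substring(cs[[1]], d$start, d$end))
    expect_equal(again$value, d$value)
    expect_equal(again$unit, d$unit)
  }
  expect_equal(nrow(extract_dose("PROPRANOLOL TAB")), 0L)
  expect_equal(nrow(extract_dose("")), 0L)
  expect_equal(nrow(extract_dose(NA_character_)), 0L)
})

test_that("multiple doses in one string are returned left to right", {
  d <- extract_dose("TAKE 10MG THEN 20 MG THEN (1.5 MEQ)")
  expect_equal(d$value, c(10, 20, 1.5))
  expect_equal(d$unit, c("MG", "MG", "MEQ"))
  expect_true(all(diff(d$start) > 0))
})

test_that("schedule phrases map to their codes and daily multipliers", {
  cases <- list(
    list("AT BEDTIME", "QHS", 1L),
    list("ONCE DAILY", "QD", 1L),
    list("TWICE DAILY", "BID", 2L),
    list("TAKE ONE CAPSULE BY MOUTH THREE TIMES A DAY", "TID", 3L),
    list("FOUR TIMES A DAY", "QID", 4L)
  )
  for (cs in cases) {
    s <- extract_schedule(cs[[1]])
    expect_equal(s$code, cs[[2]], info = cs[[1]])
    expect_equal(s$per_day, cs[[3]], info = cs[[1]])
  }
  expect_equal(extract_schedule("")$code, "UNKNOWN")
  expect_equal(extract_schedule("10MG MOUTH DAILY(1000)")$code, "UNKNOWN")

  wk <- extract_schedule("20MG MOUTH MONDAY, WEDNESDAY AND FRIDAY")
  expect_equal(wk$code, "WEEKLY_DAYS")
  expect_equal(wk$per_week, 3L)
  expect_true(is.na(wk$per_day))

  ad <- extract_schedule(paste("TAKE AS DIRECTED BY MOUTH AS INSTRUCTED",
                               "BY VA ANTICOAGULATION CLINIC"))
  expect_equal(ad$code, "AS_DIRECTED")

  # as-needed wins over any frequency cue present in the same sig
  expect_equal(extract_schedule("AS NEEDED AT BEDTIME")$code, "PRN")
})

test_that("quantity words multiply the administered dose", {
  expect_equal(extract_quantity("TAKE ONE CAPSULE BY MOUTH THREE TIMES A DAY"), 1L)
  expect_equal(extract_quantity("TAKE TWO TABLETS BY MOUTH ONCE DAILY"), 2L)
  expect_equal(extract_quantity("TAKE 3 TABS DAILY"), 3L)
  expect_equal(extract_quantity("162MG MOUTH"), 1L)
  expect_equal(extract_quantity(""), 1L)
  # a quantity word needs an administration unit next to it
  expect_equal(extract_quantity("ONE OF THE DOCTORS SAID TWICE"), 1L)
})

test_that("total daily dose is dose x quantity x per-day, unit preserved", {
  expect_equal(total_daily_dose(list(value = 300, unit = "MG"), 1,
                                schedule_code("TID")),
               list(value = 900, unit = "MG"))
  expect_equal(total_daily_dose(list(value = 10, unit = "MG"), 2,
                                schedule_code("Q12H")),
               list(value = 40, unit = "MG"))
  expect_null(total_daily_dose(list(value = 50, unit = "MG"), 1,
                               schedule_code("PRN")))
  expect_null(total_daily_dose(NULL, 1, schedule_code("TID")))
  # multiplicative consistency and unit conservation
  for (u in c("MG", "MCG", "MEQ")) {
    a <- total_daily_dose(list(value = 7, unit = u), 2, schedule_code("QID"))
    b <- total_daily_dose(list(value = 14, unit = u), 2, schedule_code("QID"))
    expect_equal(b$value, 2 * a$value)
    expect_equal(a$unit, u)
  }
})

test_that("schedule abbreviations carry the fixed per-day mapping", {
  map <- c(QD = 1L, QAM = 1L, QHS = 1L, BID = 2L, TID = 3L, QID = 4L,
           Q4H = 6L, Q12H = 2L)
  for (code in names(map)) {
    expect_equal(schedule_code(code)$per_day, map[[code]], info = code)
  }
  for (code in c("PRN", "AS_DIRECTED", "UNKNOWN")) {
    s <- schedule_code(code)
    expect_true(is.na(s$per_day) && is.na(s$per_week), info = code)
  }
})

test_that("the worked gabapentin example parses to 900 MG daily", {
  e <- raw_medication_entry("GABAPENTIN 300 MG, CAP",
                            "TAKE ONE CAPSULE BY MOUTH THREE TIMES A DAY")
  p <- parse_entry(e)
  expect_equal(p$dose$value, 300)
  expect_equal(p$dose$unit, "MG")
  expect_equal(p$dose$source_field, "NAME")
  expect_equal(p$schedule$code, "TID")
  expect_equal(p$total_daily_dose, list(value = 900, unit = "MG"))
  expect_equal(p$status, "OK")
})

test_that("sig dose wins over name dose and conflicts are surfaced", {
  p <- parse_entry(raw_medication_entry(
    "ASPIRIN, ENTERIC COATED(81 MG) TAB, EC", "162MG MOUTH"))
  expect_equal(p$dose$value, 162)
  expect_equal(p$dose$source_field, "SIG")
  expect_equal(p$conflict_dose$value, 81)
  expect_setequal(p$status, c("DOSE_CONFLICT", "NO_SCHEDULE"))
  expect_null(p$total_daily_dose)

  # agreeing doses in both fields are not a conflict
  q <- parse_entry(raw_medication_entry("DRUG 10MG TAB", "10MG ONCE DAILY"))
  expect_null(q$conflict_dose)
  expect_equal(q$status, "OK")
})

test_that("parsing never fails and always retains the raw entry verbatim", {
  entries <- list(
    raw_medication_entry("WARFARIN NA 5MG TAB",
                         paste("TAKE AS DIRECTED BY MOUTH AS INSTRUCTED BY VA",
                               "ANTICOAGULATION CLINIC (TO PREVENT BLOOD CLOTS)")),
    raw_medication_entry("FUROSEMIDE TAB", "20MG MOUTH MONDAY, WEDNESDAY AND FRIDAY"),
    raw_medication_entry("???", ""),
    raw_medication_entry("LISINOPRIL TAB", "10MG MOUTH DAILY(1000)")
  )
  for (e in entries) {
    p <- parse_entry(e)
    expect_s3_class(p, "parsed_medication")
    expect_identical(p$raw, e)
  }
  # determinism: identical input, identical output
  e <- entries[[2]]
  expect_identical(parse_entry(e), parse_entry(e))
})

test_that("CDW-dialect schedules map straight through; NULL means unknown", {
  p <- parse_entry(raw_medication_entry("LISINOPRIL 10MG TAB", "BID",
                                        source = "CDW"))
  expect_equal(p$schedule$code, "BID")
  expect_equal(p$total_daily_dose$value, 20)
  for (sig in c("", "NULL")) {
    q <- parse_entry(raw_medication_entry("LISINOPRIL 10MG TAB", sig,
                                          source = "CDW"))
    expect_equal(q$schedule$code, "UNKNOWN", info = sig)
  }
  # free-text phrases are not interpreted in the CDW dialect
  r <- parse_entry(raw_medication_entry("X 10MG TAB", "TWICE DAILY",
                                        source = "CDW"))
  expect_equal(r$schedule$code, "UNKNOWN")
})

test_that("the pattern registry is extensible via configuration", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("schedule_phrases:",
               "  'every morning': QAM",
               "dose_units:", "  - MG", "  - MCG", "  - MEQ", "  - ML"),
             cfg)
  pat <- read_patterns(cfg)
  expect_equal(extract_schedule("TAKE EVERY MORNING", pat)$code, "QAM")
  expect_equal(extract_dose("5 ML", pat)$unit, "ML")
  # defaults survive for keys the file does not mention
  expect_equal(extract_quantity("TAKE TWO TABS", pat), 2L)
  unlink(cfg)
})
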