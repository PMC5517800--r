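test_that("comorbidity flags scan ICD-9 category prefixes", {
  expect_equal(comorbidity_flags(c("401.1")), c(htn = TRUE, dm = FALSE))
  expect_equal(comorbidity_flags(c("250.00", "401.9")),
               c(htn = TRUE, dm = TRUE))
  expect_equal(comorbidity_flags(character(0)), c(htn = FALSE, dm = FALSE))
  expect_equal(comorbidity_flags(c("272.4", "V58.69")),
               c(htn = FALSE, dm = FALSE))
  # secondary hypertension categories count too
  expect_equal(comorbidity_flags("405.99")[["htn"]], TRUE)
  # malformed codes are skipped with a warning, not an error
  expect_warning(fl <- comorbidity_flags(c("garbage!", "401.9")),
                 "malformed")
  expect_true(fl[["htn"]])
})

test_that("drugs of interest are counted after exclusion, deduplicated by base name", {
  f <- example_formulary()
  meds <- list(
    raw_medication_entry("GABAPENTIN 300 MG, CAP"),
    raw_medication_entry("GABAPENTIN 100 MG, CAP"),     # same drug, renewal
    raw_medication_entry("LISINOPRIL 10MG TAB"),
    raw_medication_entry("MULTIVITAMIN TAB"),           # excluded class
    raw_medication_entry("LANCETS, BLOOD GLUCOSE"),     # supply
    raw_medication_entry("SERTRALINE 50 MG TAB")
  )
  expect_equal(count_drugs_of_interest(meds, f), 3L)
  expect_equal(count_drugs_of_interest(list(), f), 0L)
})

test_that("a single-patient grid cell reads back its tallies", {
  f <- example_formulary()
  meds <- lapply(c("GABAPENTIN 300 MG, CAP", "LISINOPRIL 10MG TAB",
                   "SERTRALINE 50 MG TAB", "FUROSEMIDE 20 MG TAB",
                   "SIMVASTATIN 20 MG TAB", "OMEPRAZOLE 20 MG CAP"),
                 raw_medication_entry)
  p <- patient_snapshot("A1", 78, c("401.9", "250.00"), "2015-11-12",
                        medications = meds)
  grid <- build_screening_grid(list(p), as.Date(c("2015-11-11", "2015-11-25")),
                               formulary = f)
  cell <- grid$cells[grid$cells$age_band == "75-84" &
                       grid$cells$drug_count == "6", ]
  expect_equal(cell$n_total, 1L)
  expect_equal(cell$n_both, 1L)
  expect_equal(cell$n_htn_only, 0L)
  expect_equal(sum(grid$cells$n_total), 1L)
})

test_that("grid cell counts equal a brute-force per-patient tally", {
  f <- example_formulary()
  pol <- classification_policy()
  window <- as.Date(c("2015-11-11", "2015-11-25"))
  for (seed in c(11, 23)) {
    coh <- generate_patient_cohort(generator_spec(seed = seed, n = 100))
    grid <- build_screening_grid(coh$patients, window, formulary = f,
                                 policy = pol)
    ref <- brute_force_grid_tally(coh$patients, window, default_age_bands(),
                                  f, pol)
    # partition: totals sum to the number of in-window patients
    expect_equal(sum(grid$cells$n_total), nrow(ref))
    for (i in seq_len(nrow(grid$cells))) {
      cell <- grid$cells[i, ]
      sub <- ref[ref$age_band == cell$age_band &
                   ref$drug_count == cell$drug_count, , drop = FALSE]
      expect_equal(cell$n_total, nrow(sub))
      expect_equal(cell$n_htn_only, sum(sub$htn & !sub$dm))
      expect_equal(cell$n_dm_only, sum(sub$dm & !sub$htn))
      expect_equal(cell$n_both, sum(sub$htn & sub$dm))
      expect_lte(cell$n_htn_only + cell$n_dm_only + cell$n_both,
                 cell$n_total)
    }
  }
})

test_that("the grid is invariant to cohort input ordering", {
  coh <- generate_patient_cohort(generator_spec(seed = 5, n = 60))
  window <- as.Date(c("2015-11-11", "2015-11-25"))
  f <- example_formulary()
  g1 <- build_screening_grid(coh$patients, window, formulary = f)
  g2 <- build_screening_grid(rev(coh$patients), window, formulary = f)
  expect_equal(g1$cells, g2$cells)
  expect_equal(g1$assignments, g2$assignments)
})

test_that("ages outside all bands go to an explicit 'other' band", {
  f <- example_formulary()
  p <- patient_snapshot("K1", 40, "401.9", "2015-11-12",
                        medications = list(raw_medication_entry("LISINOPRIL 10MG TAB")))
  grid <- build_screening_grid(list(p), as.Date(c("2015-11-11", "2015-11-25")),
                               formulary = f)
  expect_equal(sum(grid$cells$n_total), 1L)
  expect_equal(grid$assignments$age_band, "other")
})

test_that("a patient with several in-window appointments is counted once, at the earliest", {
  f <- example_formulary()
  mk <- function(d) patient_snapshot("D1", 70, "401.9", d,
                                     medications = list())
  grid <- build_screening_grid(list(mk("2015-11-20"), mk("2015-11-12")),
                               as.Date(c("2015-11-11", "2015-11-25")),
                               formulary = f)
  expect_equal(sum(grid$cells$n_total), 1L)
  expect_equal(grid$assignments$appointment_date, as.Date("2015-11-12"))
  # half-open window: the end date itself is out
  grid2 <- build_screening_grid(list(mk("2015-11-25")),
                                as.Date(c("2015-11-11", "2015-11-25")),
                                formulary = f)
  expect_equal(sum(grid2$cells$n_total), 0L)
})

test_that("patient lists honor cell selection, ordering and disjointness", {
  coh <- generate_patient_cohort(generator_spec(seed = 9, n = 80))
  window <- as.Date(c("2015-11-11", "2015-11-25"))
  grid <- build_screening_grid(coh$patients, window,
                               formulary = example_formulary())
  # selecting every cell returns every in-window patient
  all_pat <- list_patients_in_cells(grid, grid$cells)
  expect_length(all_pat, length(grid$patients))
  dates <- vapply(all_pat, function(p) as.numeric(p$appointment_date),
                  numeric(1))
  expect_true(!is.unsorted(dates))

  # disjoint selections add up
  nz <- grid$cells[grid$cells$n_total > 0, ]
  if (nrow(nz) >= 2) {
    a <- list_patients_in_cells(grid, nz[1, ])
    b <- list_patients_in_cells(grid, nz[2, ])
    ab <- list_patients_in_cells(grid, nz[1:2, ])
    expect_length(ab, length(a) + length(b))
  }
  expect_length(list_patients_in_cells(grid, grid$cells[0, ]), 0)
  expect_error(list_patients_in_cells(
    grid, data.frame(age_band = "0-1", drug_count = "99")), "not present")
})
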