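ehr_panel <- function(age = 50, ast = 40, alt = 25, plt = 200) {
  panel_state(age, list(
    AST = lab_result("AST", ast, "2015-10-01"),
    ALT = lab_result("ALT", alt, "2015-10-02"),
    PLATELETS = lab_result("PLATELETS", plt, "2015-10-03"),
    CD4 = lab_result("CD4", 500, "2015-09-01")))
}

test_that("FIB-4 formula matches hand-computed values and homogeneity", {
  expect_equal(compute_fib4(50, 40, 25, 200), 2.0)     # (50*40)/(200*5)
  expect_equal(compute_fib4(60, 30, 36, 150), 2.0)     # (60*30)/(150*6)
  expect_equal(compute_fib4(65, 80, 64, 100), 6.5)     # (65*80)/(100*8)
  # doubling platelets halves the index
  expect_equal(compute_fib4(50, 40, 25, 400), 1.0)
  expect_error(compute_fib4(50, -1, 25, 200), "positive")
  expect_error(compute_fib4(0, 40, 25, 200), "positive")
})

test_that("range classification: strict thresholds, closed middle interval", {
  expect_equal(fib4_range(1.0), "LOW")
  expect_equal(fib4_range(1.45), "INDETERMINATE")
  expect_equal(fib4_range(2.0), "INDETERMINATE")
  expect_equal(fib4_range(3.25), "INDETERMINATE")
  expect_equal(fib4_range(3.26), "HIGH")
  expect_equal(fib4_range(2.0, c(0.5, 1.5)), "HIGH")
  # oracle equivalence on many random values
  withr::with_seed(77, {
    v <- runif(1000, 0.01, 6)
    got <- vapply(v, fib4_range, character(1))
    want <- ifelse(v < 1.45, "LOW", ifelse(v > 3.25, "HIGH", "INDETERMINATE"))
    expect_equal(got, want)
  })
})

test_that("a complete AUTO panel derives FIB-4; missing components leave it absent", {
  st <- ehr_panel()
  expect_equal(st$fib4_mode, "AUTO")
  expect_equal(st$fib4_value, 2.0)
  expect_equal(st$fib4_range, "INDETERMINATE")

  st2 <- apply_field_edit(st, "ALT", NULL)   # clear one component
  expect_null(st2$fib4_value)
  expect_null(st2$fib4_range)
  # and the original state is untouched (pure function)
  expect_equal(st$fib4_value, 2.0)
})

test_that("editing a component while AUTO recomputes the index", {
  st <- ehr_panel()
  st2 <- apply_field_edit(st, "ALT", 100)
  expect_equal(st2$fib4_value, compute_fib4(50, 40, 100, 200))
  expect_equal(st2$labs$ALT$origin, "USER")
  expect_true(is.na(st2$labs$ALT$result_date))
  st3 <- apply_field_edit(st2, "PLATELETS", 50)
  expect_equal(st3$fib4_value, compute_fib4(50, 40, 100, 50))
  expect_equal(st3$fib4_range, "HIGH")
})

test_that("a manual override removes the three component values", {
  st <- ehr_panel()
  man <- apply_field_edit(st, "FIB4_RANGE", "HIGH")
  expect_equal(man$fib4_mode, "MANUAL")
  expect_equal(man$fib4_range, "HIGH")
  expect_null(man$labs$AST)
  expect_null(man$labs$ALT)
  expect_null(man$labs$PLATELETS)
  expect_false(is.null(man$labs$CD4))      # pass-through labs survive

  # entering a component returns to AUTO, starting from empty components
  back <- apply_field_edit(man, "AST", 40)
  expect_equal(back$fib4_mode, "AUTO")
  expect_null(back$fib4_value)
  back <- apply_field_edit(back, "ALT", 25)
  expect_null(back$fib4_value)
  back <- apply_field_edit(back, "PLATELETS", 200)
  expect_equal(back$fib4_value, 2.0)

  # clearing the override also returns to AUTO with FIB-4 unknown
  cleared <- apply_field_edit(man, "FIB4_RANGE", NULL)
  expect_equal(cleared$fib4_mode, "AUTO")
  expect_null(cleared$fib4_range)

  # a manual numeric value classifies itself against the thresholds
  mv <- apply_field_edit(st, "FIB4_VALUE", 4.0)
  expect_equal(mv$fib4_mode, "MANUAL")
  expect_equal(mv$fib4_range, "HIGH")
  expect_null(mv$labs$PLATELETS)
})

test_that("unknown fields are rejected with no partial update", {
  st <- ehr_panel()
  expect_error(apply_field_edit(st, "POTASSIUM", 4), "unknown panel field")
  expect_error(apply_field_edit(st, "fib4_mode", "MANUAL"), "unknown")
})

test_that("the recency view dates EHR labs and marks user entries undated", {
  st <- ehr_panel()
  v <- lab_recency_view(st)
  expect_equal(nrow(v), 4L)
  expect_true(all(!is.na(v$result_date[v$origin == "EHR"])))

  st2 <- apply_field_edit(st, "AST", 55)
  v2 <- lab_recency_view(st2)
  expect_true(is.na(v2$result_date[v2$analyte == "AST"]))
  expect_equal(v2$origin[v2$analyte == "AST"], "USER")

  empty <- panel_state(50)
  expect_equal(nrow(lab_recency_view(empty)), 0L)
})

test_that("invariants hold along random edit trajectories", {
  fields <- c("AST", "ALT", "PLATELETS", "FIB4_VALUE", "FIB4_RANGE", "CD4")
  withr::with_seed(123, {
    for (rep in 1:300) {
      st <- if (runif(1) < 0.5) ehr_panel()
            else panel_state(60, analytes = "CD4")
      for (step in seq_len(sample(1:8, 1))) {
        field <- sample(fields, 1)
        value <- if (runif(1) < 0.25) NULL
        else if (field == "FIB4_RANGE") sample(c("LOW", "INDETERMINATE", "HIGH"), 1)
        else round(runif(1, 1, 300), 1)
        st <- apply_field_edit(st, field, value)
        expect_silent(validate_panel_state(st))
        if (st$fib4_mode == "MANUAL") {
          expect_true(is.null(st$labs$AST) && is.null(st$labs$ALT) &&
                        is.null(st$labs$PLATELETS))
        }
      }
    }
  })
})
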