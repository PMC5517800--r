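#' Compute the FIB-4 liver fibrosis index
#'
#' FIB-4 = (age x AST) / (platelets x sqrt(ALT)), with AST and ALT in U/L,
#' platelets in 10^9/L and age in years.
#'
#' @param age years, > 0.
#' @param ast aspartate aminotransferase, U/L, > 0.
#' @param alt alanine aminotransferase, U/L, > 0.
#' @param platelets platelet count, 10^9/L, > 0.
#' @return a finite positive number.
#' @examples
#' compute_fib4(50, 40, 25, 200)  # 2.0
#' @export
compute_fib4 <- function(age, ast, alt, platelets) {
  vals <- c(age = age, ast = ast, alt = alt, platelets = platelets)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all FIB-4 inputs must be finite and positive")
  }
  (age * ast) / (platelets * sqrt(alt))
}

#' Classify a FIB-4 value into a range
#'
#' `LOW` strictly below `t_low`, `HIGH` strictly above `t_high`, otherwise
#' `INDETERMINATE` (the boundary values fall in the closed middle interval).
#' Defaults 1.45 / 3.25 follow the standard FIB-4 cut-points.
#'
#' @param value positive FIB-4 value.
#' @param thresholds numeric `c(t_low, t_high)`, `t_low < t_high`.
#' @return `"LOW"`, `"INDETERMINATE"` or `"HIGH"`.
#' @export
fib4_range <- function(value, thresholds = c(1.45, 3.25)) {
  stopifnot(is.numeric(value), value > 0,
            length(thresholds) == 2L, thresholds[1] < thresholds[2])
  if (value < thresholds[1]) "LOW"
  else if (value > thresholds[2]) "HIGH"
  else "INDETERMINATE"
}

FIB4_COMPONENTS <- c("AST", "ALT", "PLATELETS")

#' Create a lab result
#'
#' @param analyte analyte name (e.g. `"AST"`, `"ALT"`, `"PLATELETS"`, or any
#'   pass-through analyte).
#' @param value positive number.
#' @param result_date the date the value was obtained; required for
#'   EHR-origin results, absent (`NA`) for user-entered ones.
#' @param origin `"EHR"` or `"USER"`.
#' @return an object of class `lab_result`.
#' @export
lab_result <- function(analyte, value, result_date = NA,
                       origin = c("EHR", "USER")) {
  origin <- match.arg(origin)
  stopifnot(is.numeric(value), is.finite(value), value > 0)
  result_date <- as.Date(result_date)
  if (origin == "EHR" && is.na(result_date)) {
    stop("EHR-origin lab results must carry a result date")
  }
  if (origin == "USER") result_date <- as.Date(NA)
  structure(list(analyte = toupper(analyte), value = value,
                 result_date = result_date, origin = origin),
            class = "lab_result")
}

#' Create a lab panel state with dependent FIB-4 fields
#'
#' The panel has two modes. In `AUTO` mode, whenever AST, ALT and platelet
#' values are all present, the FIB-4 value and range are derived from them;
#' if any component is absent the FIB-4 fields are absent too. In `MANUAL`
#' mode the user has overridden the FIB-4 range (or value) directly, and the
#' three component labs are not used and so removed — the two never coexist.
#' All transitions go through [apply_field_edit()], which preserves these
#' invariants.
#'
#' @param age patient age in years, > 0 (FIB-4 uses it).
#' @param labs named list of [lab_result()] objects (names are analyte
#'   names); may include pass-through analytes beyond the three FIB-4
#'   components.
#' @param thresholds FIB-4 range cut-points `c(t_low, t_high)`.
#' @param analytes additional pass-through analyte names the panel accepts
#'   edits for even when no value is currently stored; the editable roster
#'   is always the union of the FIB-4 components, the initial labs and this
#'   argument.
#' @return an object of class `panel_state` with fields `age`, `labs`,
#'   `analytes` (the editable roster), `fib4_mode` (`"AUTO"`/`"MANUAL"`),
#'   `fib4_value`, `fib4_range` and `thresholds`.
#' @examples
#' st <- panel_state(50, list(
#'   AST = lab_result("AST", 40, "2015-10-01"),
#'   ALT = lab_result("ALT", 25, "2015-10-01"),
#'   PLATELETS = lab_result("PLATELETS", 200, "2015-10-01")))
#' st$fib4_value
#' @export
panel_state <- function(age, labs = list(), thresholds = c(1.45, 3.25),
                        analytes = character(0)) {
  stopifnot(is.numeric(age), age > 0)
  if (length(labs)) {
    stopifnot(!is.null(names(labs)),
              all(vapply(labs, inherits, logical(1), "lab_result")))
    names(labs) <- toupper(names(labs))
  }
  roster <- unique(c(FIB4_COMPONENTS, names(labs), toupper(analytes)))
  st <- structure(list(age = as.numeric(age), labs = labs,
                       analytes = roster, fib4_mode = "AUTO",
                       fib4_value = NULL, fib4_range = NULL,
                       thresholds = thresholds),
                  class = "panel_state")
  refresh_fib4(st)
}

# Recompute the dependent FIB-4 fields of an AUTO-mode state.
refresh_fib4 <- function(state) {
  if (state$fib4_mode == "AUTO") {
    present <- vapply(FIB4_COMPONENTS, function(a) !is.null(state$labs[[a]]),
                      logical(1))
    if (all(present)) {
      v <- compute_fib4(state$age,
                        state$labs$AST$value,
                        state$labs$ALT$value,
                        state$labs$PLATELETS$value)
      state$fib4_value <- v
      state$fib4_range <- fib4_range(v, state$thresholds)
    } else {
      state$fib4_value <- NULL
      state$fib4_range <- NULL
    }
  }
  state
}

#' Validate panel-state invariants
#'
#' Stops unless: in `MANUAL` mode no component lab (AST/ALT/platelets) is
#' stored; in `AUTO` mode the FIB-4 fields are present and correct exactly
#' when all three components are; and any present range agrees with the
#' thresholds applied to the value.
#'
#' @param state a [panel_state()].
#' @return `TRUE`, invisibly.
#' @export
validate_panel_state <- function(state) {
  stopifnot(inherits(state, "panel_state"),
            state$fib4_mode %in% c("AUTO", "MANUAL"))
  comp <- vapply(FIB4_COMPONENTS, function(a) !is.null(state$labs[[a]]),
                 logical(1))
  if (state$fib4_mode == "MANUAL") {
    if (any(comp)) stop("MANUAL mode must not store component lab values")
  } else {
    if (all(comp)) {
      expected <- compute_fib4(state$age, state$labs$AST$value,
                               state$labs$ALT$value,
                               state$labs$PLATELETS$value)
      if (is.null(state$fib4_value) ||
          abs(state$fib4_value - expected) > 1e-9) {
        stop("AUTO mode FIB-4 value out of sync with its components")
      }
      if (!identical(state$fib4_range,
                     fib4_range(state$fib4_value, state$thresholds))) {
        stop("FIB-4 range disagrees with thresholds")
      }
    } else if (!is.null(state$fib4_value) || !is.null(state$fib4_range)) {
      stop("AUTO mode with missing components must have no FIB-4 fields")
    }
  }
  invisible(TRUE)
}

#' Apply a user edit to a panel field
#'
#' The dependent-field contract:
#' * Editing AST, ALT or platelets while in `AUTO` mode sets (or clears) that
#'   lab as a user-entered value and recomputes FIB-4.
#' * Editing a component while in `MANUAL` mode first returns to `AUTO` mode
#'   (discarding the manual override; the previously removed components are
#'   not restored), then applies the edit — FIB-4 stays absent until all
#'   three components have been re-entered.
#' * Setting `FIB4_RANGE` (to `LOW`/`INDETERMINATE`/`HIGH`) or `FIB4_VALUE`
#'   switches to `MANUAL` mode and removes the three component labs, which
#'   are no longer used.
#' * Clearing `FIB4_RANGE`/`FIB4_VALUE` in `MANUAL` mode returns to `AUTO`
#'   with all components absent (FIB-4 unknown).
#' * Any other analyte already on the panel is a pass-through field: its
#'   value is set or cleared with no effect on FIB-4.
#'
#' The input state is never modified; an edit naming an unknown field is
#' rejected with an error and no partial update.
#'
#' @param state a [panel_state()].
#' @param field one of `"AST"`, `"ALT"`, `"PLATELETS"`, `"FIB4_VALUE"`,
#'   `"FIB4_RANGE"`, or a pass-through analyte on the panel's roster.
#' @param value new value (positive number for labs and `FIB4_VALUE`; a range
#'   label for `FIB4_RANGE`), or `NULL`/`NA` to clear the field.
#' @return the new `panel_state`.
#' @export
apply_field_edit <- function(state, field, value = NULL) {
  stopifnot(inherits(state, "panel_state"),
            is.character(field), length(field) == 1L)
  field <- toupper(field)
  clear <- is.null(value) || (length(value) == 1L && is.na(value))
  new <- state

  if (field %in% FIB4_COMPONENTS) {
    if (new$fib4_mode == "MANUAL") {
      new$fib4_mode <- "AUTO"          # leaving the override; nothing restored
      new$fib4_value <- NULL
      new$fib4_range <- NULL
    }
    if (clear) {
      new$labs[[field]] <- NULL
    } else {
      new$labs[[field]] <- lab_result(field, as.numeric(value),
                                      origin = "USER")
    }
    new <- refresh_fib4(new)
  } else if (field == "FIB4_RANGE") {
    if (clear) {
      new$fib4_mode <- "AUTO"
      new$fib4_value <- NULL
      new$fib4_range <- NULL
      new <- refresh_fib4(new)   # components absent after an override; else recompute
    } else {
      value <- match.arg(toupper(value), c("LOW", "INDETERMINATE", "HIGH"))
      new$fib4_mode <- "MANUAL"
      for (a in FIB4_COMPONENTS) new$labs[[a]] <- NULL
      new$fib4_value <- NULL
      new$fib4_range <- value
    }
  } else if (field == "FIB4_VALUE") {
    if (clear) {
      new$fib4_mode <- "AUTO"
      new$fib4_value <- NULL
      new$fib4_range <- NULL
      new <- refresh_fib4(new)
    } else {
      v <- as.numeric(value)
      stopifnot(is.finite(v), v > 0)
      new$fib4_mode <- "MANUAL"
      for (a in FIB4_COMPONENTS) new$labs[[a]] <- NULL
      new$fib4_value <- v
      new$fib4_range <- fib4_range(v, new$thresholds)
    }
  } else if (field %in% state$analytes) {
    if (clear) {
      new$labs[[field]] <- NULL
    } else {
      new$labs[[field]] <- lab_result(field, as.numeric(value),
                                      origin = "USER")
    }
  } else {
    stop("unknown panel field: ", field)
  }
  validate_panel_state(new)
  new
}

#' Expanded lab view with result dates
#'
#' Lets the user judge how recent each laboratory value is: every present
#' lab with its value and the date it was obtained; user-entered values are
#' undated (`NA`).
#'
#' @param state a [panel_state()].
#' @return data frame with columns `analyte`, `value`, `result_date`,
#'   `origin` (zero rows for an empty panel).
#' @export
lab_recency_view <- function(state) {
  stopifnot(inherits(state, "panel_state"))
  if (!length(state$labs)) {
    return(data.frame(analyte = character(0), value = numeric(0),
                      result_date = as.Date(character(0)),
                      origin = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    analyte = vapply(state$labs, `[[`, character(1), "analyte"),
    value = vapply(state$labs, `[[`, numeric(1), "value"),
    result_date = as.Date(vapply(state$labs, function(l) {
      as.numeric(l$result_date)
    }, numeric(1)), origin = "1970-01-01"),
    origin = vapply(state$labs, `[[`, character(1), "origin"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.panel_state <- function(x, ...) {
  cat(sprintf("<panel_state> age %g, mode %s\n", x$age, x$fib4_mode))
  if (!is.null(x$fib4_value)) {
    cat(sprintf("  FIB-4: %.3g (%s)\n", x$fib4_value, x$fib4_range))
  } else if (!is.null(x$fib4_range)) {
    cat(sprintf("  FIB-4 range (manual): %s\n", x$fib4_range))
  } else {
    cat("  FIB-4: <unknown>\n")
  }
  v <- lab_recency_view(x)
  if (nrow(v)) print(v)
  invisible(x)
}
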