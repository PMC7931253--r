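# ---- parameter objects -------------------------------------------------

#' Atwater energy conversion factors
#'
#' General Atwater factors: 4 kcal per gram of carbohydrate, 4 kcal per gram
#' of protein, 9 kcal per gram of fat.
#'
#' @param cho_kcal_per_g,protein_kcal_per_g,fat_kcal_per_g kcal per gram of
#'   each macronutrient; all strictly positive.
#' @return A list of class `atwater_factors`.
#' @export
atwater_factors <- function(cho_kcal_per_g = 4, protein_kcal_per_g = 4,
                            fat_kcal_per_g = 9) {
  f <- list(cho = cho_kcal_per_g, protein = protein_kcal_per_g,
            fat = fat_kcal_per_g)
  if (any(unlist(f) <= 0) || anyNA(unlist(f))) {
    abort_foodexch("invalid_component", "Atwater factors must be > 0")
  }
  structure(f, class = "atwater_factors")
}

#' Kjeldahl nitrogen-to-protein factor
#'
#' Crude protein estimated as total Kjeldahl nitrogen times a food-specific
#' factor; the default 6.38 is the dairy-type factor.
#'
#' @param nitrogen_to_protein dimensionless factor, > 0.
#' @return A list of class `kjeldahl_factor`.
#' @export
kjeldahl_factor <- function(nitrogen_to_protein = 6.38) {
  if (!is.numeric(nitrogen_to_protein) || anyNA(nitrogen_to_protein) ||
      nitrogen_to_protein <= 0) {
    abort_foodexch("invalid_component", "Kjeldahl factor must be > 0")
  }
  structure(list(nitrogen_to_protein = nitrogen_to_protein),
            class = "kjeldahl_factor")
}

# ---- records -----------------------------------------------------------

prox_components <- c("moisture", "ash", "cho", "protein", "fat")
prox_columns <- c("name", "food_class", prox_components, "energy_kcal",
                  "cho_source")

#' Construct a proximate composition record
#'
#' One food's per-100 g edible-portion composition. If `cho` is omitted it is
#' completed by difference ([cho_by_difference()]) and `cho_source` is set to
#' `"by_difference"`; if `energy_kcal` is omitted it is derived as the
#' round-half-up Atwater energy of the stored components. Components outside
#' \[0, 100\] g raise an `invalid_component` error at construction time.
#'
#' @param name food identifier.
#' @param food_class `"dish"` or `"sweet"`.
#' @param moisture,ash,protein,fat grams per 100 g edible portion.
#' @param cho grams carbohydrate per 100 g, or `NULL` to derive by difference.
#' @param energy_kcal kcal per 100 g, or `NULL` to derive (Atwater, rounded
#'   half-up to integer for display).
#' @param cho_source `"measured_printed"` or `"by_difference"`; defaults to
#'   the former when `cho` is supplied, the latter when it is derived.
#' @param factors [atwater_factors()] used when energy is derived.
#' @return A one-row data frame of class `proximate_table` with columns
#'   `name`, `food_class`, `moisture`, `ash`, `cho`, `protein`, `fat`,
#'   `energy_kcal`, `cho_source`.
#' @examples
#' proximate_record("Baba ghanouj", "dish", 91.5, 1.1, 1.1, 1.8)
#' @export
proximate_record <- function(name, food_class = c("dish", "sweet"),
                             moisture, ash, protein, fat,
                             cho = NULL, energy_kcal = NULL,
                             cho_source = NULL, factors = atwater_factors()) {
  food_class <- match.arg(food_class)
  for (comp in c("moisture", "ash", "protein", "fat")) {
    check_nonneg(get(comp), comp)
  }
  if (is.null(cho)) {
    cho <- cho_by_difference(moisture, ash, protein, fat)
    cho_source <- cho_source %||% "by_difference"
  } else {
    check_nonneg(cho, "cho")
    cho_source <- cho_source %||% "measured_printed"
  }
  cho_source <- match.arg(cho_source, c("measured_printed", "by_difference"))
  comps <- c(moisture, ash, cho, protein, fat)
  if (any(comps > 100)) {
    abort_foodexch("invalid_component", sprintf(
      "components of '%s' must be <= 100 g/100 g", name))
  }
  if (is.null(energy_kcal)) {
    energy_kcal <- round_half_up(atwater_energy(cho, protein, fat, factors))
  } else {
    check_nonneg(energy_kcal, "energy_kcal")
  }
  out <- data.frame(name = as.character(name), food_class = food_class,
                    moisture = moisture, ash = ash, cho = cho,
                    protein = protein, fat = fat, energy_kcal = energy_kcal,
                    cho_source = cho_source, stringsAsFactors = FALSE)
  class(out) <- c("proximate_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a data frame of proximate records
#'
#' Checks that the required columns are present and structurally sound (this
#' is the parse-time contract; scientific consistency is the job of
#' [validate_records()]).
#'
#' @param df a data frame with the [proximate_record()] columns.
#' @return `df` with class `proximate_table`, invisibly usable downstream.
#' @export
as_proximate_table <- function(df) {
  missing_cols <- setdiff(prox_columns, names(df))
  if (length(missing_cols)) {
    abort_foodexch("schema_error", paste0(
      "missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (comp in c(prox_components, "energy_kcal")) {
    v <- df[[comp]]
    if (!is.numeric(v)) {
      abort_foodexch("schema_error", sprintf("column '%s' is not numeric", comp))
    }
    bad <- which(!is.na(v) & (v < 0 | (comp != "energy_kcal" & v > 100)))
    if (length(bad)) {
      abort_foodexch("schema_error", sprintf(
        "column '%s', row %d ('%s'): value %g outside [0, 100]",
        comp, bad[1], df$name[bad[1]], v[bad[1]]))
    }
  }
  if (!all(class(df) == c("proximate_table", "data.frame"))) {
    class(df) <- c("proximate_table", "data.frame")
  }
  df
}

# ---- operations --------------------------------------------------------

#' Carbohydrate by difference
#'
#' Completes a proximate row under the mass-closure constraint: total
#' carbohydrate is whatever is left of 100 g after moisture, ash, protein
#' and fat.
#'
#' @param moisture,ash,protein,fat grams per 100 g edible portion; vectors
#'   recycle as usual.
#' @return grams carbohydrate per 100 g; always >= 0.
#' @section Errors: `foodexch_invalid_component` if any input is negative;
#'   `foodexch_negative_difference` if the four components sum above 100 g
#'   (a closure-impossible row).
#' @examples
#' cho_by_difference(91.5, 1.1, 1.1, 1.8)  # 4.5
#' @export
cho_by_difference <- function(moisture, ash, protein, fat) {
  check_nonneg(moisture, "moisture"); check_nonneg(ash, "ash")
  check_nonneg(protein, "protein");   check_nonneg(fat, "fat")
  s <- moisture + ash + protein + fat
  if (any(s > 100 + 1e-9)) {
    abort_foodexch("negative_difference", sprintf(
      "moisture+ash+protein+fat = %g exceeds 100 g; carbohydrate by difference would be negative",
      max(s)))
  }
  pmax(100 - s, 0)
}

#' Atwater energy of a macronutrient triple
#'
#' Unrounded energy in kcal per 100 g: `cho*4 + protein*4 + fat*9` with the
#' default factors. Composition tables print this rounded half-up to the
#' integer; apply [round_half_up()] for the display value.
#'
#' @param cho,protein,fat grams per 100 g.
#' @param factors an [atwater_factors()] object.
#' @return unrounded kcal per 100 g.
#' @examples
#' atwater_energy(1.1, 29.7, 8.2)                 # 197
#' round_half_up(atwater_energy(20.3, 3.8, 2.9))  # 123 (122.5 rounds up)
#' @export
atwater_energy <- function(cho, protein, fat, factors = atwater_factors()) {
  check_nonneg(cho, "cho"); check_nonneg(protein, "protein")
  check_nonneg(fat, "fat")
  factors$cho * cho + factors$protein * protein + factors$fat * fat
}

#' Crude protein from Kjeldahl nitrogen
#'
#' @param n grams total Kjeldahl nitrogen.
#' @param factor a [kjeldahl_factor()] object (default 6.38, dairy-type).
#' @return grams crude protein.
#' @examples
#' protein_from_nitrogen(1)    # 6.38
#' protein_from_nitrogen(2.5)  # 15.95
#' @export
protein_from_nitrogen <- function(n, factor = kjeldahl_factor()) {
  check_nonneg(n, "nitrogen")
  factor$nitrogen_to_protein * n
}

#' Mass-closure residual of proximate records
#'
#' Signed departure of the five-component sum from 100 g. Zero means the row
#' honours the closure constraint implicit in carbohydrate-by-difference.
#'
#' @param records a `proximate_table` (or compatible data frame).
#' @return numeric vector of residuals in grams, one per row.
#' @section Errors: `foodexch_missing_field` if any component is `NA`.
#' @export
mass_closure_residual <- function(records) {
  records <- as_proximate_table(records)
  comps <- records[prox_components]
  if (anyNA(comps)) {
    i <- which(rowSums(is.na(comps)) > 0)[1]
    abort_foodexch("missing_field", sprintf(
      "row %d ('%s') has missing proximate component(s)", i, records$name[i]))
  }
  with(records, moisture + ash + cho + protein + fat - 100)
}

# ---- auditing ----------------------------------------------------------

finding_codes <- c("closure_violation", "energy_mismatch",
                   "negative_component", "missing_field",
                   "derived_vs_printed_cho_mismatch")

new_findings <- function(food_name = character(), code = character(),
                         magnitude = numeric(), message = character()) {
  data.frame(food_name = food_name, code = code, magnitude = magnitude,
             message = message, stringsAsFactors = FALSE)
}

#' Audit proximate records for internal consistency
#'
#' Reports (never repairs) three kinds of inconsistency per row:
#' a closure violation when the five components do not sum to 100 g within
#' `closure_tol`; an energy mismatch when the printed energy differs from
#' the unrounded Atwater energy of the stored components by more than
#' `energy_tol`; and, for rows whose carbohydrate was measured or printed
#' rather than derived, a disagreement between that value and carbohydrate
#' by difference beyond `closure_tol`. Missing or negative components are
#' reported as findings rather than raised as errors.
#'
#' @param records a `proximate_table`; `validate_record()` is the
#'   single-record spelling of the same function.
#' @param closure_tol grams; default 0.2 g accepts every internally
#'   consistent row of the packaged dish table (max observed residual 0.1 g)
#'   while rejecting the inconsistent sweet rows.
#' @param energy_tol kcal; default 1.5 kcal, the largest discrepancy that
#'   pure display rounding of a consistent row can produce here.
#' @param factors [atwater_factors()] used for the energy recomputation.
#' @return A data frame of findings with columns `food_name`, `code`
#'   (one of `closure_violation`, `energy_mismatch`, `negative_component`,
#'   `missing_field`, `derived_vs_printed_cho_mismatch`), `magnitude`
#'   (signed residual, grams or kcal according to `code`) and `message`.
#'   Zero rows means every record is consistent.
#' @examples
#' rec <- proximate_record("ok", "dish", 70, 1, 5, 4, cho = 20,
#'                         energy_kcal = 136)
#' validate_record(rec)  # no findings
#' @export
validate_records <- function(records, closure_tol = 0.2, energy_tol = 1.5,
                             factors = atwater_factors()) {
  records <- as_proximate_table(records)
  out <- new_findings()
  add <- function(name, code, magnitude, msg) {
    out <<- rbind(out, new_findings(name, code, magnitude, msg))
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    comps <- unlist(r[prox_components])
    missing <- names(comps)[is.na(comps)]
    if (is.na(r$energy_kcal)) missing <- c(missing, "energy_kcal")
    for (m in missing) {
      add(r$name, "missing_field", NA_real_, sprintf("field '%s' is missing", m))
    }
    neg <- names(comps)[!is.na(comps) & comps < 0]
    for (m in neg) {
      add(r$name, "negative_component", comps[[m]],
          sprintf("component '%s' is negative (%g g)", m, comps[[m]]))
    }
    if (anyNA(comps) || length(neg)) next
    resid <- sum(comps) - 100
    if (abs(resid) > closure_tol) {
      add(r$name, "closure_violation", resid, sprintf(
        "components sum to %.1f g (residual %+.1f g > %.1f g tolerance)",
        sum(comps), resid, closure_tol))
    }
    if (!is.na(r$energy_kcal)) {
      atw <- atwater_energy(r$cho, r$protein, r$fat, factors)
      if (abs(atw - r$energy_kcal) > energy_tol) {
        add(r$name, "energy_mismatch", atw - r$energy_kcal, sprintf(
          "Atwater energy %.1f kcal vs printed %.10g kcal (difference %+.1f kcal)",
          atw, r$energy_kcal, atw - r$energy_kcal))
      }
    }
    if (identical(r$cho_source, "measured_printed")) {
      # raw difference, not cho_by_difference(): the audit must report (not
      # raise) rows whose four components already exceed 100 g
      diff_cho <- 100 - (r$moisture + r$ash + r$protein + r$fat)
      if (abs(diff_cho - r$cho) > closure_tol) {
        add(r$name, "derived_vs_printed_cho_mismatch", diff_cho - r$cho,
            sprintf("carbohydrate by difference %.1f g vs printed %.10g g",
                    diff_cho, r$cho))
      }
    }
  }
  out
}

#' @rdname validate_records
#' @param record a one-row `proximate_table`.
#' @export
validate_record <- function(record, closure_tol = 0.2, energy_tol = 1.5,
                            factors = atwater_factors()) {
  validate_records(record, closure_tol, energy_tol, factors)
}
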