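# ---- parameter objects -------------------------------------------------

#' Macronutrient grams per exchange
#'
#' One exchange carries 15 g carbohydrate, 7 g protein or 5 g fat.
#'
#' @param cho_g,protein_g,fat_g grams of the macronutrient in one exchange;
#'   strictly positive.
#' @return A list of class `exchange_quantum`.
#' @export
exchange_quantum <- function(cho_g = 15, protein_g = 7, fat_g = 5) {
  q <- list(cho = cho_g, protein = protein_g, fat = fat_g)
  if (any(unlist(q) <= 0) || anyNA(unlist(q))) {
    abort_foodexch("invalid_component", "exchange quanta must be > 0")
  }
  structure(q, class = "exchange_quantum")
}

#' Wheeler round-off serving bands
#'
#' The round-off method assigns 0, 0.5 or 1 serving to a single food portion
#' from the grams of each macronutrient it contains. The published bands are
#' stated on integer grams (carbohydrate 1--5, 6--10, 11--20; protein 0--3,
#' 4--10; fat 0--2, 3, 4--7); here they are extended to continuous half-open
#' intervals with cut points at 5/10/20 g carbohydrate, 3 g protein and
#' 2/3.5/7 g fat so fractional laboratory values are classifiable. A portion
#' with 0 g carbohydrate maps to 0 servings.
#'
#' @param cho_cuts,protein_cuts,fat_cuts increasing numeric cut points; band
#'   i is `(cuts[i-1], cuts[i]]` with the first band starting closed at 0.
#' @param cho_servings,protein_servings,fat_servings servings value of each
#'   band, drawn from 0, 0.5, 1.
#' @return A list of class `wheeler_bands`.
#' @export
wheeler_bands <- function(cho_cuts = c(5, 10, 20), cho_servings = c(0, 0.5, 1),
                          protein_cuts = c(3, 10), protein_servings = c(0, 1),
                          fat_cuts = c(2, 3.5, 7), fat_servings = c(0, 0.5, 1)) {
  bands <- list(cho = list(cuts = cho_cuts, servings = cho_servings),
                protein = list(cuts = protein_cuts, servings = protein_servings),
                fat = list(cuts = fat_cuts, servings = fat_servings))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (is.unsorted(b$cuts, strictly = TRUE) ||
        length(b$cuts) != length(b$servings) ||
        !all(b$servings %in% c(0, 0.5, 1))) {
      abort_foodexch("invalid_component", sprintf(
        "%s bands must have strictly increasing cuts and servings in {0, 0.5, 1}", nm))
    }
  }
  structure(bands, class = "wheeler_bands")
}

band_lookup <- function(x, band, nutrient) {
  check_nonneg(x, nutrient)
  if (any(x > band$cuts[length(band$cuts)] + 1e-9)) {
    abort_foodexch("out_of_band", sprintf(
      "%s of %g g per portion exceeds the %g g band ceiling; reduce the portion or use exchanges_per_100g()",
      nutrient, max(x), band$cuts[length(band$cuts)]),
      nutrient = nutrient, value = max(x))
  }
  # (cuts[i-1], cuts[i]] with [0, cuts[1]] first; epsilon keeps exact cut
  # points (possibly a few ulps high in float) in their closed band
  band$servings[findInterval(x, band$cuts + 1e-9) + 1L]
}

#' Wheeler round-off servings of a single portion
#'
#' @param cho,protein,fat grams per portion; must lie within the band
#'   domains (by default cho <= 20, protein <= 10, fat <= 7), else a
#'   `foodexch_out_of_band` error identifies the offending nutrient --
#'   the portion is too large for single-serving classification.
#' @param bands a [wheeler_bands()] object.
#' @return named numeric `c(cho = , protein = , fat = )`, each 0, 0.5 or 1.
#' @examples
#' wheeler_servings(8, 0, 0)  # half a carbohydrate serving
#' wheeler_servings(0, 0, 3)  # half a fat serving
#' @export
wheeler_servings <- function(cho, protein, fat, bands = wheeler_bands()) {
  c(cho = band_lookup(cho, bands$cho, "cho"),
    protein = band_lookup(protein, bands$protein, "protein"),
    fat = band_lookup(fat, bands$fat, "fat"))
}

# ---- serving derivation ------------------------------------------------

#' Grams of food yielding one exchange
#'
#' The serving of a food that supplies exactly one exchange of a nutrient is
#' `100 * quantum / amount_per_100g` grams; composition tables print it
#' rounded half-up to the integer gram.
#'
#' @param amount_per_100g grams of the nutrient per 100 g of food; > 0.
#' @param quantum_g grams of the nutrient in one exchange.
#' @return data frame with columns `unrounded` (grams, full precision) and
#'   `grams` (integer serving).
#' @section Errors: `foodexch_zero_nutrient` when `amount_per_100g` is 0 (no
#'   finite serving yields an exchange).
#' @examples
#' grams_for_one_exchange(75.4, 15)  # 19.89... -> 20 g
#' @export
grams_for_one_exchange <- function(amount_per_100g, quantum_g) {
  check_nonneg(amount_per_100g, "amount_per_100g")
  if (any(amount_per_100g == 0)) {
    abort_foodexch("zero_nutrient",
                   "nutrient amount is 0 g/100 g; no finite serving yields one exchange")
  }
  unrounded <- 100 * quantum_g / amount_per_100g
  data.frame(unrounded = unrounded, grams = as.integer(round_half_up(unrounded)))
}

#' Serving specification
#'
#' @param grams positive integer serving mass.
#' @param household_measure free-text kitchen descriptor, e.g. "1/2 cup".
#' @return A list of class `serving_spec`.
#' @export
serving_spec <- function(grams, household_measure = "") {
  if (!is.numeric(grams) || anyNA(grams) || any(grams < 1) ||
      any(grams != as.integer(grams))) {
    abort_foodexch("invalid_component", "serving grams must be a positive integer")
  }
  structure(list(grams = as.integer(grams),
                 household_measure = as.character(household_measure)),
            class = "serving_spec")
}

#' Quarter-quantized exchanges in 100 g
#'
#' Nutrient amount divided by its exchange quantum, quantized to the nearest
#' quarter exchange (ties rounding up) -- the granularity published exchange
#' lists use.
#'
#' @param records a `proximate_table`.
#' @param quanta an [exchange_quantum()].
#' @return data frame with columns `name`, `cho_ex`, `protein_ex`, `fat_ex`.
#' @examples
#' rec <- proximate_record("Batata mehchi", "dish", 69.5, 1.8, 5, 5.7,
#'                         cho = 18, energy_kcal = 143)
#' exchanges_per_100g(rec)$cho_ex  # 1.25
#' @export
exchanges_per_100g <- function(records, quanta = exchange_quantum()) {
  records <- as_proximate_table(records)
  data.frame(name = records$name,
             cho_ex = round_quarter(records$cho / quanta$cho),
             protein_ex = round_quarter(records$protein / quanta$protein),
             fat_ex = round_quarter(records$fat / quanta$fat),
             stringsAsFactors = FALSE)
}

#' Scale per-100 g values to a serving
#'
#' Macronutrient amounts scale linearly with serving mass and are reported
#' truncated at one decimal; energy scales the per-100 g display energy the
#' same way (a trailing ".0" renders as an integer in the writers).
#'
#' @param records a `proximate_table`.
#' @param grams serving mass in grams (scalar or one per record).
#' @return data frame with columns `name`, `grams`, `cho_g`, `protein_g`,
#'   `fat_g`, `energy_kcal` (reported values) and `*_raw` full-precision
#'   columns.
#' @examples
#' rec <- proximate_record("Falafel", "dish", 31.3, 3.4, 13.3, 15.6,
#'                         cho = 36.5, energy_kcal = 339)
#' scale_to_serving(rec, 40)[c("cho_g", "protein_g", "fat_g", "energy_kcal")]
#' # 14.6, 5.3, 6.2, 135.6
#' @export
scale_to_serving <- function(records, grams) {
  records <- as_proximate_table(records)
  check_nonneg(grams, "serving grams")
  k <- grams / 100
  data.frame(name = records$name, grams = grams,
             cho_g = trunc_decimal(records$cho * k),
             protein_g = trunc_decimal(records$protein * k),
             fat_g = trunc_decimal(records$fat * k),
             energy_kcal = trunc_decimal(records$energy_kcal * k),
             cho_g_raw = records$cho * k,
             protein_g_raw = records$protein * k,
             fat_g_raw = records$fat * k,
             energy_kcal_raw = records$energy_kcal * k,
             stringsAsFactors = FALSE)
}

#' Serving sized to one carbohydrate exchange
#'
#' The convention behind sweet servings in published exchange lists: size
#' the portion so it carries one carbohydrate exchange (about 15 g CHO).
#' The household measure is left empty for the caller to annotate.
#'
#' @inheritParams exchanges_per_100g
#' @return integer grams, one per record.
#' @section Errors: `foodexch_zero_nutrient` if a record has 0 g
#'   carbohydrate.
#' @examples
#' rec <- proximate_record("Moushabak", "sweet", 13.5, 0.05, 2.1, 16.4,
#'                         cho = 71.5, energy_kcal = 410)
#' serving_for_one_cho_exchange(rec)  # 21
#' @export
serving_for_one_cho_exchange <- function(records, quanta = exchange_quantum()) {
  records <- as_proximate_table(records)
  grams_for_one_exchange(records$cho, quanta$cho)$grams
}

# ---- category reconciliation ------------------------------------------

exchange_categories <- c("starch", "vegetable", "fat", "sugar", "other_cho",
                         "whole_milk", "lean_meat", "medium_fat_meat",
                         "high_fat_meat", "reduced_fat_milk_or_meat",
                         "protein_generic")

#' Per-exchange macronutrient profiles of the exchange categories
#'
#' Grams of carbohydrate, protein and fat carried by one exchange of each
#' category. Only the generic quanta (15 g CHO, 7 g protein, 5 g fat) come
#' from the round-off method itself; the per-category split follows the
#' widely used exchange-list conventions (starch 15/3/0, vegetable 5/2/0,
#' milk 12/8/fat-tier, meat 0/7/fat-tier) and is configuration, not
#' measurement -- override it freely. The `reduced_fat_milk_or_meat`
#' category keeps the source table's ambiguous "RFM" token (glossed
#' "reduced fat meat" but applied to milk puddings) and defaults to a
#' reduced-fat milk profile.
#'
#' @param overrides optional data frame with columns `category`, `cho_g`,
#'   `protein_g`, `fat_g` replacing the default rows it names.
#' @return data frame with one row per category.
#' @export
category_profiles <- function(overrides = NULL) {
  prof <- data.frame(
    category = exchange_categories,
    cho_g    = c(15, 5, 0, 5, 15, 12, 0, 0, 0, 12, 0),
    protein_g = c(3, 2, 0, 0, 0, 8, 7, 7, 7, 8, 7),
    fat_g    = c(0, 0, 5, 0, 0, 8, 3, 5, 8, 5, 0),
    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    unknown <- setdiff(overrides$category, prof$category)
    if (length(unknown)) {
      abort_foodexch("unknown_category", paste0(
        "unknown exchange categor(ies): ", paste(unknown, collapse = ", ")))
    }
    i <- match(overrides$category, prof$category)
    prof[i, c("cho_g", "protein_g", "fat_g")] <-
      overrides[c("cho_g", "protein_g", "fat_g")]
  }
  prof
}

#' Audit an exchange annotation against measured macros
#'
#' Residual macronutrients left unexplained by a food's annotated exchange
#' decomposition: `measured - sum(count * category profile)` per nutrient.
#' Category membership is not computable from proximates, so annotations
#' are accepted as input and only audited, never inferred.
#'
#' @param measured named numeric with elements `cho`, `protein`, `fat`
#'   (grams in the portion).
#' @param annotation a parsed exchange string (data frame with `count` and
#'   `category`, see [parse_exchange_string()]).
#' @param profiles a [category_profiles()] table.
#' @return named numeric residuals `c(cho = , protein = , fat = )` in grams.
#' @examples
#' reconcile_categories(c(cho = 14.6, protein = 5.3, fat = 6.2),
#'                      parse_exchange_string("1 starch, 1 MFM"))
#' # cho -0.4, protein -4.7, fat +1.2
#' @export
reconcile_categories <- function(measured, annotation,
                                 profiles = category_profiles()) {
  stopifnot(all(c("cho", "protein", "fat") %in% names(measured)))
  i <- match(annotation$category, profiles$category)
  if (anyNA(i)) {
    abort_foodexch("unknown_category", paste0(
      "annotation uses unknown categor(ies): ",
      paste(annotation$category[is.na(i)], collapse = ", ")))
  }
  explained <- c(cho = sum(annotation$count * profiles$cho_g[i]),
                 protein = sum(annotation$count * profiles$protein_g[i]),
                 fat = sum(annotation$count * profiles$fat_g[i]))
  c(cho = unname(measured["cho"] - explained["cho"]),
    protein = unname(measured["protein"] - explained["protein"]),
    fat = unname(measured["fat"] - explained["fat"]))
}
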