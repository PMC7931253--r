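# Synthetic proximate compositions: the generator states the world the
# pipeline assumes (five components closing to 100 g, class-specific
# marginal ranges bracketing the packaged table's extremes) and nothing
# more; nutrient correlations beyond closure are deliberately not modelled.

default_ranges <- list(
  dish  = list(moisture = c(30, 92), ash = c(0.2, 3.5),
               protein = c(1, 30), fat = c(0.5, 23)),
  sweet = list(moisture = c(0.5, 56), ash = c(0.1, 2),
               protein = c(2, 20), fat = c(6, 43)))

#' Profile for the synthetic composition generator
#'
#' Class-specific uniform ranges for the four measured components
#' (carbohydrate is always completed by difference). Defaults bracket the
#' packaged reference table: dishes span moisture 30--92 g, ash 0.2--3.5 g,
#' protein 1--30 g, fat 0.5--23 g per 100 g; sweets span 0.5--56, 0.1--2,
#' 2--20 and 6--43 g.
#'
#' @param class_label `"dish"` or `"sweet"`.
#' @param component_ranges optional named list of `c(min, max)` pairs for
#'   `moisture`, `ash`, `protein`, `fat`, replacing the class defaults.
#' @param seed integer seed; part of the generator's public contract
#'   (identical profile, identical output).
#' @return list of class `generator_profile`.
#' @export
generator_profile <- function(class_label = c("dish", "sweet"),
                              component_ranges = NULL, seed = 1L) {
  class_label <- match.arg(class_label)
  ranges <- default_ranges[[class_label]]
  if (!is.null(component_ranges)) {
    ranges[names(component_ranges)] <- component_ranges
  }
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || anyNA(r) || r[1] > r[2] || r[1] < 0 || r[2] > 100) {
      abort_foodexch("invalid_component", sprintf(
        "range for '%s' must be 0 <= min <= max <= 100", nm))
    }
  }
  structure(list(class_label = class_label, ranges = ranges,
                 seed = as.integer(seed)), class = "generator_profile")
}

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate synthetic proximate records
#'
#' Draws moisture, ash, protein and fat uniformly within the profile ranges,
#' rejection-sampling (budget 1000 tries per record) until their sum is
#' below 100 g; carbohydrate is then completed by difference and energy by
#' Atwater (display value, rounded half-up). Rejection rather than
#' renormalization keeps the marginal ranges honest. Generated records pass
#' [validate_records()] by construction.
#'
#' @param n number of records (>= 0).
#' @param profile a [generator_profile()].
#' @param factors [atwater_factors()] for the derived energy.
#' @return a `proximate_table` of `n` rows, names `syn_<class>_001` ...;
#'   `cho_source` is `"by_difference"` throughout.
#' @section Errors: `foodexch_generation_failure` if the retry budget is
#'   exhausted (ranges incompatible with closure).
#' @examples
#' generate_compositions(3, generator_profile("dish", seed = 7))
#' @export
generate_compositions <- function(n, profile = generator_profile(),
                                  factors = atwater_factors()) {
  stopifnot(is.numeric(n), n >= 0)
  n <- as.integer(n)
  empty <- proximate_record("x", "dish", 50, 1, 5, 5)[0, ]
  if (n == 0) return(empty)
  r <- profile$ranges
  rows <- with_preserved_rng(profile$seed, lapply(seq_len(n), function(i) {
    for (try in seq_len(1000)) {
      m <- stats::runif(1, r$moisture[1], r$moisture[2])
      a <- stats::runif(1, r$ash[1], r$ash[2])
      p <- stats::runif(1, r$protein[1], r$protein[2])
      f <- stats::runif(1, r$fat[1], r$fat[2])
      if (m + a + p + f < 100) {
        return(proximate_record(
          sprintf("syn_%s_%03d", profile$class_label, i),
          profile$class_label, m, a, p, f, factors = factors))
      }
    }
    abort_foodexch("generation_failure", sprintf(
      "record %d: 1000 rejection-sampling tries without closure; ranges are incompatible with a 5-component sum of 100 g", i))
  }))
  out <- do.call(rbind, rows)
  class(out) <- c("proximate_table", "data.frame")
  out
}

#' Corrupt the mass closure of a record
#'
#' Shifts one component by `delta` grams without recomputing carbohydrate or
#' energy, so the record's closure residual moves by exactly `delta` --
#' emulating the internally inconsistent rows found in published tables.
#'
#' @param record a one-row `proximate_table`.
#' @param delta grams to add (may be negative).
#' @param target one of `moisture`, `ash`, `cho`, `protein`, `fat`.
#' @return the shifted record; `cho_source` becomes `"measured_printed"`
#'   because the stored carbohydrate no longer closes the row.
#' @section Errors: `foodexch_invalid_component` if the shift would drive
#'   the component negative.
#' @export
corrupt_closure <- function(record, delta, target = "cho") {
  record <- as_proximate_table(record)
  stopifnot(nrow(record) == 1)
  target <- match.arg(target, prox_components)
  value <- record[[target]] + delta
  if (value < 0) {
    abort_foodexch("invalid_component", sprintf(
      "shifting %s by %g g would make it negative (%g g)", target, delta, value))
  }
  record[[target]] <- value
  if (delta != 0) record$cho_source <- "measured_printed"
  record
}
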