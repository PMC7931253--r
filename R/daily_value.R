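#' Daily reference intake for percent-daily-value profiling
#'
#' Defaults follow a 2000 kcal reference diet: 275 g/d carbohydrate (55% of
#' energy), 50 g/d protein (10%) and 78 g/d fat (35%).
#'
#' @param cho_g,protein_g,fat_g grams per day; strictly positive.
#' @param energy_kcal kcal per day; strictly positive.
#' @return A list of class `daily_reference`.
#' @export
daily_reference <- function(cho_g = 275, protein_g = 50, fat_g = 78,
                            energy_kcal = 2000) {
  ref <- list(cho_g = cho_g, protein_g = protein_g, fat_g = fat_g,
              energy_kcal = energy_kcal)
  if (any(unlist(ref) <= 0) || anyNA(unlist(ref))) {
    abort_foodexch("invalid_component", "daily reference values must be > 0")
  }
  structure(ref, class = "daily_reference")
}

#' Percent daily value of 100 g portions
#'
#' Expresses each macronutrient (and energy) of a 100 g portion as a
#' percentage of the daily reference, reported at one decimal. The reporting
#' mode defaults to truncation toward zero, the convention that reproduces
#' the packaged dish table cell-for-cell (16.95 prints as 16.9, not 17.0);
#' `"half_up"` is available because some published tables use it instead.
#' Full-precision values are kept in `*_pct_raw` columns.
#'
#' @param records a `proximate_table`; every row must have `cho`, `protein`,
#'   `fat` and `energy_kcal` (else a `foodexch_missing_field` error).
#' @param ref a [daily_reference()].
#' @param mode `"truncate"` (default) or `"half_up"` reporting at one
#'   decimal.
#' @return Data frame with columns `name`, `cho_pct`, `protein_pct`,
#'   `fat_pct`, `energy_pct` (reported at one decimal) and the
#'   corresponding `*_pct_raw` full-precision columns.
#' @examples
#' rec <- proximate_record("Shawarma dajaj", "dish", 58.6, 2.4, 29.7, 8.2,
#'                         cho = 1.1, energy_kcal = 197)
#' percent_dv(rec)$protein_pct  # 59.4
#' @export
percent_dv <- function(records, ref = daily_reference(),
                       mode = c("truncate", "half_up")) {
  mode <- match.arg(mode)
  records <- as_proximate_table(records)
  need <- c("cho", "protein", "fat", "energy_kcal")
  bad <- which(rowSums(is.na(records[need])) > 0)
  if (length(bad)) {
    abort_foodexch("missing_field", sprintf(
      "row %d ('%s') is missing a component needed for %%DV",
      bad[1], records$name[bad[1]]))
  }
  report <- if (mode == "truncate") trunc_decimal else function(x) round_half_up(x, 1)
  raw <- data.frame(
    cho_pct_raw     = 100 * records$cho / ref$cho_g,
    protein_pct_raw = 100 * records$protein / ref$protein_g,
    fat_pct_raw     = 100 * records$fat / ref$fat_g,
    energy_pct_raw  = 100 * records$energy_kcal / ref$energy_kcal)
  data.frame(name = records$name,
             cho_pct = report(raw$cho_pct_raw),
             protein_pct = report(raw$protein_pct_raw),
             fat_pct = report(raw$fat_pct_raw),
             energy_pct = report(raw$energy_pct_raw),
             raw, stringsAsFactors = FALSE)
}

#' FDA-style nutrient-content claim from a percent daily value
#'
#' Labelling tiers: below 5% DV a food is a "low" source of the nutrient;
#' from 5% up to (but excluding) 20% it is a "good source"; at 20% DV or
#' more it is "high". The bands are half-open, so 19.999 is still
#' `good_source` and 20.0 is `high`.
#'
#' @param pct percent daily value, >= 0 (vectorized).
#' @return character vector over `c("low", "good_source", "high")`.
#' @examples
#' classify_claim(c(1.6, 13.2, 26.6))  # "low" "good_source" "high"
#' @export
classify_claim <- function(pct) {
  check_nonneg(pct, "percent daily value")
  c("low", "good_source", "high")[findInterval(pct, c(5, 20)) + 1L]
}

#' Batch percent-daily-value table with claims
#'
#' One row per record, preserving input order. Rows that are missing a
#' required component are reported in the `findings` attribute (a
#' [validate_records()]-style data frame) and carry `NA` cells instead of
#' aborting the batch.
#'
#' @inheritParams percent_dv
#' @return The [percent_dv()] data frame plus `cho_claim`, `protein_claim`
#'   and `fat_claim` columns (claims classify the reported one-decimal
#'   values, matching what a label would print). Attribute `findings` holds
#'   per-row missing-field reports.
#' @export
dv_table <- function(records, ref = daily_reference(),
                     mode = c("truncate", "half_up")) {
  mode <- match.arg(mode)
  records <- as_proximate_table(records)
  need <- c("cho", "protein", "fat", "energy_kcal")
  ok <- rowSums(is.na(records[need])) == 0
  cols <- c("cho_pct", "protein_pct", "fat_pct", "energy_pct",
            "cho_pct_raw", "protein_pct_raw", "fat_pct_raw", "energy_pct_raw")
  out <- data.frame(name = records$name, stringsAsFactors = FALSE)
  for (col in cols) out[[col]] <- rep(NA_real_, nrow(out))
  for (col in c("cho_claim", "protein_claim", "fat_claim")) {
    out[[col]] <- rep(NA_character_, nrow(out))
  }
  if (any(ok)) {
    p <- percent_dv(records[ok, , drop = FALSE], ref, mode)
    out[ok, cols] <- p[cols]
    out$cho_claim[ok] <- classify_claim(p$cho_pct)
    out$protein_claim[ok] <- classify_claim(p$protein_pct)
    out$fat_claim[ok] <- classify_claim(p$fat_pct)
  }
  findings <- new_findings()
  for (i in which(!ok)) {
    m <- need[is.na(unlist(records[i, need]))]
    findings <- rbind(findings, new_findings(
      records$name[i], "missing_field", NA_real_,
      sprintf("field '%s' is missing", m)))
  }
  attr(out, "findings") <- findings
  out
}
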