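# Fixture schemas (UTF-8, one header row, dot decimals):
#   table2_composition.csv: name, class, moisture, ash, cho, protein, fat,
#     energy, dv_cho, dv_protein, dv_fat, dv_energy, flags
#   table4_exchanges.csv: name, exchanges_100g, serving_text,
#     exchanges_serving, cho, protein, fat, energy, flags
# Known inconsistencies of the source tables are carried as ;-separated
# deviation flags rather than silently corrected.

#' Path to a packaged fixture
#'
#' @param file file name under `extdata`; with no argument, lists them.
#' @return absolute path (or file listing).
#' @export
foodexch_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "foodexch")))
  }
  path <- system.file("extdata", file, package = "foodexch", mustWork = FALSE)
  if (!nzchar(path)) {
    abort_foodexch("schema_error", sprintf("no packaged fixture '%s'", file))
  }
  path
}

read_schema_csv <- function(path, required) {
  if (!file.exists(path)) {
    abort_foodexch("schema_error", sprintf("file not found: %s", path))
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 encoding = "UTF-8"),
                 error = function(e) {
                   abort_foodexch("schema_error", sprintf(
                     "cannot parse %s: %s", path, conditionMessage(e)))
                 })
  if (nrow(df) == 0) {
    abort_foodexch("schema_error", sprintf("%s contains no data rows", path))
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_foodexch("schema_error", sprintf(
      "%s: missing column(s) %s", path, paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Load a proximate-composition table
#'
#' Reads the packaged 65-food composition fixture (30 dishes + 35 sweets)
#' or any CSV in the same schema. Printed values are preserved verbatim:
#' carbohydrate is loaded with `cho_source = "measured_printed"` so the
#' auditor can compare it against carbohydrate-by-difference, and the
#' printed percent-daily-value block (when present) is retained in the
#' `printed_dv` attribute for audit.
#'
#' @param path CSV path; `NULL` (default) loads the packaged fixture.
#' @return A `proximate_table` with the [proximate_record()] columns plus
#'   `flags`; attributes `printed_dv` (data frame of the printed %DV cells,
#'   or `NULL`) travel with it.
#' @section Errors: `foodexch_schema_error` with row/column coordinates on
#'   empty files, missing columns, non-numeric or out-of-range cells.
#' @examples
#' tab <- load_table2()
#' table(tab$food_class)  # 30 dishes, 35 sweets
#' @export
load_table2 <- function(path = NULL) {
  path <- path %||% foodexch_example("table2_composition.csv")
  df <- read_schema_csv(path, c("name", "class", "moisture", "ash", "cho",
                                "protein", "fat", "energy"))
  if (anyDuplicated(df$name)) {
    abort_foodexch("schema_error", sprintf(
      "%s: duplicated food name '%s'", path, df$name[anyDuplicated(df$name)]))
  }
  if (!all(df$class %in% c("dish", "sweet"))) {
    abort_foodexch("schema_error", sprintf(
      "%s: class must be 'dish' or 'sweet' (row %d)",
      path, which(!df$class %in% c("dish", "sweet"))[1]))
  }
  out <- data.frame(name = df$name, food_class = df$class,
                    moisture = as.numeric(df$moisture),
                    ash = as.numeric(df$ash), cho = as.numeric(df$cho),
                    protein = as.numeric(df$protein),
                    fat = as.numeric(df$fat),
                    energy_kcal = as.numeric(df$energy),
                    cho_source = "measured_printed",
                    flags = if ("flags" %in% names(df)) as.character(df$flags) else "",
                    stringsAsFactors = FALSE)
  out$flags[is.na(out$flags)] <- ""
  out <- as_proximate_table(out)
  dv_cols <- c("dv_cho", "dv_protein", "dv_fat", "dv_energy")
  if (all(dv_cols %in% names(df))) {
    attr(out, "printed_dv") <- data.frame(name = df$name,
                                          df[dv_cols],
                                          stringsAsFactors = FALSE)
  }
  out
}

#' Load the exchange-list fixture
#'
#' The packaged transcription of the source exchange list: per-100 g and
#' per-serving exchange strings (verbatim, including their decimal-comma
#' dialect), serving texts, printed per-serving amounts, and deviation
#' flags marking cells that are inconsistent with the table's own rules
#' (`serving_floor`, `fat_cell_deviates`, `energy_cell_deviates`).
#'
#' @param path CSV path; `NULL` (default) loads the packaged fixture.
#' @return data frame with columns `name`, `exchanges_100g`, `serving_text`,
#'   `exchanges_serving`, `cho`, `protein`, `fat`, `energy`, `flags`, plus
#'   parsed `serving_g` and `household_measure`.
#' @export
load_table4 <- function(path = NULL) {
  path <- path %||% foodexch_example("table4_exchanges.csv")
  df <- read_schema_csv(path, c("name", "exchanges_100g", "serving_text",
                                "exchanges_serving", "cho", "protein",
                                "fat", "energy"))
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  serv <- parse_serving_measure(df$serving_text)
  df$serving_g <- serv$grams
  df$household_measure <- serv$household_measure
  df
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

# ---- serving-text parser ----------------------------------------------

#' Parse a serving-size text
#'
#' Serving cells read like `"100 g (1/2 cup)"` or, for sweets where the
#' gram unit is implied, `"23 (1 piece)"`: a leading integer gram mass with
#' an optional `g` mark, then a parenthesized household measure.
#'
#' @param text character vector of serving texts.
#' @return data frame with columns `grams` (integer) and
#'   `household_measure`; use [serving_spec()] on a row for the typed
#'   object.
#' @section Errors: `foodexch_unparsable_serving` retaining the raw text.
#' @examples
#' parse_serving_measure("40 g (2 patty balls)")  # 40, "2 patty balls"
#' @export
parse_serving_measure <- function(text) {
  if (!length(text) || any(!nzchar(trimws(text)))) {
    abort_foodexch("unparsable_serving", "empty serving text")
  }
  m <- regmatches(text, regexec("^\\s*([0-9]+)\\s*(?:g\\b)?\\s*(?:\\((.*)\\))?\\s*$",
                                text))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    abort_foodexch("unparsable_serving", sprintf(
      "cannot parse serving text: '%s'", text[bad][1]), text = text[bad][1])
  }
  data.frame(grams = as.integer(vapply(m, `[`, "", 2)),
             household_measure = trimws(vapply(m, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

# ---- exchange-string parser -------------------------------------------

category_aliases <- c(
  "starch" = "starch", "vegetable" = "vegetable", "fat" = "fat",
  "sugar" = "sugar", "othercho" = "other_cho", "other_cho" = "other_cho",
  "wm" = "whole_milk", "wholemilk" = "whole_milk",
  "lm" = "lean_meat", "leanmeat" = "lean_meat",
  "mf" = "medium_fat_meat", "mfm" = "medium_fat_meat",
  "mediumfatmeat" = "medium_fat_meat",
  "hfm" = "high_fat_meat", "highfatmeat" = "high_fat_meat",
  "rfm" = "reduced_fat_milk_or_meat",
  "reducedfatmeat" = "reduced_fat_milk_or_meat",
  "reducedfatmilk" = "reduced_fat_milk_or_meat",
  "protein" = "protein_generic", "proteingeneric" = "protein_generic")

category_render <- c(
  starch = "starch", vegetable = "vegetable", fat = "fat", sugar = "sugar",
  other_cho = "other CHO", whole_milk = "WM", lean_meat = "LM",
  medium_fat_meat = "MFM", high_fat_meat = "HFM",
  reduced_fat_milk_or_meat = "RFM", protein_generic = "protein")

#' Parse an exchange-count string
#'
#' Understands the dialect of published exchange lists: tokens separated by
#' commas, counts in quarter units, category names or their abbreviations
#' in any case (`"MF"`/`"MFM"` medium-fat meat, `"WM"` whole milk,
#' `"other CHO"`/`"other-CHO"`). A comma is treated as a decimal mark --
#' including the spaced variant `"1, 25 starch"` -- exactly when it sits
#' between a digit and digits followed by a category word; otherwise it
#' separates tokens. A count glued to its category (`"0.25RFM"`) parses too.
#'
#' @param text a single exchange string; `""`/`NA` give an empty result.
#' @return data frame with columns `count` (multiples of 0.25) and
#'   `category` (canonical names, see [category_profiles()]).
#' @section Errors: `foodexch_unknown_category` for unrecognized tokens;
#'   `foodexch_malformed_count` for counts that are not quarter multiples.
#' @examples
#' parse_exchange_string("1,25 starch, 1 fat")
#' parse_exchange_string("1, 25 starch, 1 MFM")
#' @export
parse_exchange_string <- function(text) {
  empty <- data.frame(count = numeric(), category = character(),
                      stringsAsFactors = FALSE)
  if (length(text) != 1) {
    abort_foodexch("malformed_count", "parse_exchange_string() takes one string")
  }
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  # decimal-comma disambiguation: digit "," digits then a letter
  canon <- gsub("(?<=[0-9]),\\s*(?=[0-9]+\\s*[A-Za-z])", ".", text, perl = TRUE)
  tokens <- trimws(strsplit(canon, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  parse_token <- function(tok) {
    m <- regmatches(tok, regexec("^([0-9]*\\.?[0-9]+)?\\s*([A-Za-z].*)$", tok))[[1]]
    if (!length(m)) {
      abort_foodexch("unknown_category", sprintf("cannot parse token '%s'", tok))
    }
    count <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    if (abs(count - round_quarter(count)) > 1e-9) {
      abort_foodexch("malformed_count", sprintf(
        "count %s in '%s' is not a multiple of 0.25", m[2], tok))
    }
    key <- gsub("[^a-z]", "", tolower(m[3]))
    if (!key %in% names(category_aliases)) {
      abort_foodexch("unknown_category", sprintf(
        "unknown exchange category '%s' in token '%s'", m[3], tok),
        token = m[3])
    }
    data.frame(count = count, category = unname(category_aliases[key]),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(list(empty), lapply(tokens, parse_token)))
}

#' Render parsed exchange counts back to canonical text
#'
#' Canonical form uses dot decimals and the standard abbreviations, e.g.
#' `"1.25 starch, 1 fat"`; [parse_exchange_string()] of the result is the
#' identity.
#'
#' @param parsed data frame with `count` and `category`.
#' @return a single string; `""` for zero rows.
#' @export
format_exchange_string <- function(parsed) {
  if (!nrow(parsed)) return("")
  unknown <- setdiff(parsed$category, names(category_render))
  if (length(unknown)) {
    abort_foodexch("unknown_category", paste0(
      "unknown categor(ies): ", paste(unknown, collapse = ", ")))
  }
  paste(sprintf("%s %s", format(parsed$count, trim = TRUE, drop0trailing = TRUE),
                category_render[parsed$category]),
        collapse = ", ")
}

# ---- writers -----------------------------------------------------------

format_energy <- function(x) {
  # one decimal, with trailing ".0" rendered as the bare integer
  ifelse(abs(x - round(x)) < 1e-9, sprintf("%d", as.integer(round(x))),
         sprintf("%.1f", x))
}

#' Write an exchange list as CSV (and optionally markdown)
#'
#' Deterministic column order mirroring the published layout; counts use
#' canonical dot decimals, so reloading the CSV reproduces the entries.
#'
#' @param entries data frame of exchange-list entries as produced by
#'   [run_exchanges()]: `name`, `exchanges_100g`, `serving_g`,
#'   `household_measure`, `exchanges_serving`, `cho_g`, `protein_g`,
#'   `fat_g`, `energy_kcal`.
#' @param csv_path output CSV path.
#' @param md_path optional markdown output path.
#' @return `csv_path`, invisibly.
#' @export
write_exchange_list <- function(entries, csv_path, md_path = NULL) {
  cols <- c("name", "exchanges_100g", "serving_g", "household_measure",
            "exchanges_serving", "cho_g", "protein_g", "fat_g", "energy_kcal")
  missing_cols <- setdiff(cols, names(entries))
  if (length(missing_cols)) {
    abort_foodexch("schema_error", paste0(
      "entries missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- entries[cols]
  ok <- tryCatch({
    utils::write.csv(out, csv_path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    abort_foodexch("io_error", sprintf("cannot write %s: %s", csv_path,
                                       conditionMessage(ok)))
  }
  if (!is.null(md_path)) {
    writeLines(render_markdown_table(out), md_path, useBytes = TRUE)
  }
  invisible(csv_path)
}

#' Reload an exchange-list CSV written by [write_exchange_list()]
#'
#' @param csv_path path to the CSV.
#' @return the entries data frame (round-trip equal to what was written).
#' @export
read_exchange_list <- function(csv_path) {
  df <- read_schema_csv(csv_path, c("name", "exchanges_100g", "serving_g",
                                    "household_measure", "exchanges_serving",
                                    "cho_g", "protein_g", "fat_g",
                                    "energy_kcal"))
  for (col in c("household_measure", "exchanges_100g", "exchanges_serving")) {
    df[[col]][is.na(df[[col]])] <- ""
    df[[col]] <- as.character(df[[col]])
  }
  df
}

render_markdown_table <- function(df) {
  fmt_cell <- function(x) {
    if (is.numeric(x)) format(x, trim = TRUE, drop0trailing = TRUE) else
      ifelse(is.na(x), "", as.character(x))
  }
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(vapply(df[i, ], fmt_cell, ""), collapse = " | "), " |")
  }, "")
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    body)
}
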