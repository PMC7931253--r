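# foodexch

Food-composition auditing and dietary exchange-list derivation in R.

Dietitians plan meals for people with diabetes or obesity using *exchange
lists*: standardized portions that each carry a fixed macronutrient load
(one carbohydrate exchange = 15 g CHO, one protein exchange = 7 g protein,
one fat exchange = 5 g fat), so foods in the same category can be swapped
without changing the plan. Building such a list from laboratory proximate
analysis involves a chain of small, convention-laden computations that are
easy to get silently wrong — and published tables often are. `foodexch`
implements the whole chain as tested, composable functions:

- **Completion.** Carbohydrate by difference,
  `CHO = 100 − (moisture + ash + protein + fat)` g per 100 g edible
  portion, and Atwater energy `E = 4·CHO + 4·protein + 9·fat` kcal/100 g
  (displayed rounded half-up); Kjeldahl protein `6.38 × N`.
- **Auditing.** Mass-closure residuals, printed-vs-recomputed energy, and
  printed-vs-derived carbohydrate checks, reported as structured findings
  (never silently repaired).
- **%DV profiling.** Percent daily value against a 2000 kcal reference
  (275 g CHO / 50 g protein / 78 g fat) with FDA-style claim tiers:
  low < 5 % ≤ good source < 20 % ≤ high.
- **Exchange derivation.** The Wheeler round-off method (banded 0 / 0.5 / 1
  servings per portion), grams-per-exchange serving sizes
  (`100 × quantum / amount`), quarter-exchange quantization per 100 g, and
  per-serving scaling with the truncation rules published tables use.
- **Data.** A fully transcribed 65-food Eastern Mediterranean reference
  table (30 traditional dishes + 35 Arabic sweets) as plain-CSV fixtures,
  parsers for the tables' serving and exchange-string dialects, a seeded
  synthetic-composition generator with controlled closure corruption, and
  a four-subcommand CLI (`validate`, `analyze`, `exchanges`, `simulate`).

## Worked example

```r
library(foodexch)

tab <- load_table2()                 # packaged 65-food table
findings <- validate_records(tab)    # audit every row
findings[findings$food_name == "Barazik", c("code", "magnitude")]
#>                              code magnitude
#>                 closure_violation       9.2
#>                   energy_mismatch      83.1
#>   derived_vs_printed_cho_mismatch      -9.2
```

Barazik's printed components sum to 109.2 g (9.2 g over closure), its
Atwater energy recomputes 83.1 kcal above the printed 553 kcal, and the
printed 49 g CHO is 9.2 g above what by-difference allows. All 30 dish rows
pass the audit; all 35 sweet rows fail it.

```r
fal <- tab[tab$name == "Falafel", ]
percent_dv(fal)[c("cho_pct", "protein_pct", "fat_pct", "energy_pct")]
#>   cho_pct protein_pct fat_pct energy_pct
#>      13.2        26.6      20       16.9
classify_claim(26.6)
#> [1] "high"          # falafel is a "high protein" food by the 20 % DV rule

nam <- tab[tab$name == "Nammoura", ]
serving_for_one_cho_exchange(nam)    # grams carrying one 15 g CHO exchange
#> [1] 20
scale_to_serving(nam, 20)[c("cho_g", "protein_g", "fat_g", "energy_kcal")]
#>   cho_g protein_g fat_g energy_kcal
#>      15       0.6   1.7        75.2
```

A 20 g piece of nammoura is exactly one carbohydrate exchange. The same
derivation runs over a whole table from the command line:

```sh
Rscript inst/cli/foodexch exchanges \
  --annotations inst/extdata/table4_exchanges.csv --output exchanges.csv
Rscript inst/cli/foodexch validate --input my_lab_table.csv
```

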