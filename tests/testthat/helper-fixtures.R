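# Shared fixture accessors. The packaged tables are loaded once per run;
# `row_of()` pulls a single food by name.

t2_all <- load_table2()
t2_dishes <- t2_all[t2_all$food_class == "dish", ]
t2_sweets <- t2_all[t2_all$food_class == "sweet", ]
t4_all <- load_table4()
t4_sweets <- t4_all[t4_all$name %in% t2_sweets$name, ]

row_of <- function(name, tab = t2_all) {
  out <- tab[tab$name == name, ]
  stopifnot(nrow(out) == 1)
  out
}

has_flag <- foodexch:::has_flag
default_ranges_of <- function(class_label) foodexch:::default_ranges[[class_label]]

with_seed_local <- function(seed, code) withr::with_seed(seed, code)
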