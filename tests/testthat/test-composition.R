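test_that("cho_by_difference completes rows and guards its domain", {
  expect_equal(cho_by_difference(91.5, 1.1, 1.1, 1.8), 4.5)   # Baba ghanouj
  expect_equal(cho_by_difference(0, 0, 0, 0), 100)
  # Barazik's four measured components leave 39.8 g, not the printed 49 g
  expect_equal(cho_by_difference(1.5, 1.3, 15.3, 42.1), 39.8)
  expect_error(cho_by_difference(-1, 0, 0, 0), class = "foodexch_invalid_component")
  expect_error(cho_by_difference(60, 30, 20, 10), class = "foodexch_negative_difference")
  # vectorized over rows
  expect_equal(cho_by_difference(c(91.5, 0), c(1.1, 0), c(1.1, 0), c(1.8, 0)),
               c(4.5, 100))
})

test_that("atwater_energy is the 4/4/9 linear form with half-up display", {
  expect_equal(atwater_energy(1.1, 29.7, 8.2), 197)           # Shawarma dajaj
  expect_equal(atwater_energy(0, 0, 0), 0)
  # Falafel's printed CHO gives 339.6 unrounded; half-up display is 340
  # (the printed 339 arises from the by-difference CHO, see acceptance)
  expect_equal(atwater_energy(36.5, 13.3, 15.6), 339.6)
  expect_equal(round_half_up(atwater_energy(36.5, 13.3, 15.6)), 340)
  expect_equal(round_half_up(atwater_energy(36.4, 13.3, 15.6)), 339)
  expect_error(atwater_energy(-1, 0, 0), class = "foodexch_invalid_component")
  # custom factors
  expect_equal(atwater_energy(10, 10, 10, atwater_factors(4.1, 5.65, 9.4)), 191.5)
})

test_that("atwater_energy is linear in its components", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(3, 0, 50); b <- runif(3, 0, 50)
    expect_equal(atwater_energy(a[1] + b[1], a[2] + b[2], a[3] + b[3]),
                 atwater_energy(a[1], a[2], a[3]) + atwater_energy(b[1], b[2], b[3]))
  }
})

test_that("protein_from_nitrogen applies the Kjeldahl factor", {
  expect_equal(protein_from_nitrogen(1), 6.38)
  expect_equal(protein_from_nitrogen(0), 0)
  expect_equal(protein_from_nitrogen(2.5), 15.95)
  expect_equal(protein_from_nitrogen(2, kjeldahl_factor(6.25)), 12.5)
  expect_error(protein_from_nitrogen(-0.1), class = "foodexch_invalid_component")
})

test_that("mass_closure_residual reads the fixture rows correctly", {
  expect_equal(mass_closure_residual(row_of("Baba ghanouj")), 0)
  expect_equal(mass_closure_residual(row_of("Falafel")), 0.1)
  expect_equal(mass_closure_residual(row_of("Barazik")), 9.2)
  r <- row_of("Falafel"); r$fat <- NA_real_
  expect_error(mass_closure_residual(r), class = "foodexch_missing_field")
})

test_that("validate_record reports without mutating", {
  expect_identical(nrow(validate_record(row_of("Falafel"))), 0L)
  bar <- validate_record(row_of("Barazik"))
  expect_setequal(bar$code, c("closure_violation", "energy_mismatch",
                              "derived_vs_printed_cho_mismatch"))
  expect_equal(bar$magnitude[bar$code == "closure_violation"], 9.2)
  # recomputed Atwater 636.1 vs printed 553
  expect_equal(bar$magnitude[bar$code == "energy_mismatch"], 636.1 - 553)

  allcho <- proximate_record("allcho", "dish", 0, 0, 0, 0, cho = 100,
                             energy_kcal = 400)
  expect_identical(nrow(validate_record(allcho)), 0L)

  r <- row_of("Falafel"); r$protein <- NA_real_
  f <- validate_record(r)
  expect_true("missing_field" %in% f$code)

  # negatives are rejected at parse time, before the auditor ever runs
  r2 <- row_of("Falafel"); r2$fat <- -1
  expect_error(validate_record(r2), class = "foodexch_schema_error")
})

test_that("record construction derives cho and energy and enforces ranges", {
  rec <- proximate_record("Baba ghanouj", "dish", 91.5, 1.1, 1.1, 1.8)
  expect_equal(rec$cho, 4.5)
  expect_equal(rec$cho_source, "by_difference")
  expect_equal(rec$energy_kcal, 39)  # half-up of 38.6
  expect_identical(nrow(validate_record(rec)), 0L)
  expect_error(proximate_record("bad", "dish", 50, 1, 5, -2),
               class = "foodexch_invalid_component")
  expect_error(proximate_record("bad", "dish", 50, 1, 5, 5, cho = 101),
               class = "foodexch_invalid_component")
})

test_that("the 30-dish table is internally consistent", {
  resid <- mass_closure_residual(t2_dishes)
  expect_true(all(abs(resid) <= 0.2))
  diff_cho <- cho_by_difference(t2_dishes$moisture, t2_dishes$ash,
                                t2_dishes$protein, t2_dishes$fat)
  expect_true(all(abs(diff_cho - t2_dishes$cho) <= 0.1 + 1e-9))
  expect_identical(nrow(validate_records(t2_dishes)), 0L)
})
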