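test_that("CFE biomass is the fumigated-minus-unfumigated DOC difference", {
  expect_equal(cfe_biomass(350, 50), 300)
  expect_equal(cfe_biomass(50, 50), 0)
  res <- collect_qc(cfe_biomass(40, 50))
  expect_equal(res$value, -10)  # retained, not clamped
  expect_equal(res$qc$what, "negative_cfe_biomass")
})

test_that("specific activity follows dose and soil mass", {
  expect_equal(specific_activity(treatment_spec(400)), 190 / 10000)
  expect_equal(specific_activity(treatment_spec(90)), 190 / 2250)
  expect_equal(specific_activity(treatment_spec(400, activity_14c = 0)), 0)
  expect_error(specific_activity(treatment_spec(0)),
               class = "sg_undefined_specific_activity")
})

test_that("14C-traced glucose-derived biomass converts and clamps", {
  expect_equal(glucose_derived_mbc_14c(2.0, 0.1, 0.019), 100)
  expect_equal(glucose_derived_mbc_14c(1, 1, 0.019), 0)
  res <- collect_qc(glucose_derived_mbc_14c(0.5, 1, 0.019))
  expect_equal(res$value, 0)
  expect_equal(res$qc$what, "negative_14c_mbc_clamped")
  expect_error(glucose_derived_mbc_14c(1, 0, 0),
               class = "sg_undefined_specific_activity")
})

test_that("CO2 rates sit at interval midpoints and add up", {
  r <- co2_rate(0, 8, 4)
  expect_equal(r$rate, 0.5)
  expect_equal(r$t_mid, 4)
  expect_equal(co2_rate(4, 8, 0)$rate, 0)
  # additivity: two adjacent intervals reconstruct the cumulative total
  r2 <- co2_rate(c(0, 6), c(6, 24), c(3, 9))
  expect_equal(sum(r2$rate * c(6, 18)), 12)
  expect_error(co2_rate(5, 5, 1), class = "sg_bad_interval")
})

test_that("CO2 glucose fraction mixes in at% space", {
  sp <- treatment_spec(400)
  bg <- delta_to_atpercent(-27)
  expect_equal(co2_glucose_fraction(atpercent_to_delta(3 - 1e-13), sp, bg), 1,
               tolerance = 1e-9)
  expect_equal(co2_glucose_fraction(-27, sp, bg), 0)
  mid <- atpercent_to_delta((3 + bg) / 2)
  expect_equal(co2_glucose_fraction(mid, sp, bg), 0.5)
  expect_error(co2_glucose_fraction(-10, treatment_spec(0), bg),
               class = "sg_zero_c_partition")
})

test_that("storage pool carbon conversions", {
  expect_equal(phb_carbon(100), 100 * 48.044 / 86.090)
  expect_equal(round(phb_carbon(100), 2), 55.81)
  expect_equal(phb_carbon(0), 0)
  a <- runif(1, 0, 50); b <- runif(1, 0, 50)
  expect_equal(phb_carbon(a + b), phb_carbon(a) + phb_carbon(b))
  expect_equal(tag_carbon(c(`16:0` = 2, `18:2w6` = 1)), 3)
  expect_equal(tag_carbon(numeric()), 0)
  v <- c(1.2, 0.3, 2.2)
  expect_equal(tag_carbon(v), tag_carbon(rev(v)))
})

test_that("glucose-derived storage combines correction, mixing and amount", {
  sp <- treatment_spec(400)
  bg <- delta_to_atpercent(-27)
  reagent <- delta_to_atpercent(-27)
  # derivative at% equal to the corrected background -> 0
  deriv_bg <- (4 * bg + 2 * reagent) / 6
  expect_equal(glucose_derived_storage(40, deriv_bg, "PHB", sp, bg), 0)
  # fully labelled analyte -> full amount
  deriv_full <- (4 * 3 + 2 * reagent) / 6
  expect_equal(glucose_derived_storage(40, deriv_full, "PHB", sp, bg), 40,
               tolerance = 1e-9)
  # corrected at% midway between endmembers -> half the pool
  deriv_mid <- (4 * (bg + 3) / 2 + 2 * reagent) / 6
  expect_equal(glucose_derived_storage(40, deriv_mid, "PHB", sp, bg), 20)
  # FAME route uses the fatty-acid C count
  deriv_fa <- (16 * (bg + 3) / 2 + 1 * reagent) / 17
  expect_equal(glucose_derived_storage(10, deriv_fa, "16:1w7", sp, bg), 5)
  expect_error(glucose_derived_storage(10, 1.1, "not-a-lipid", sp, bg),
               class = "sg_unknown_fatty_acid")
})

test_that("glucose-derived C never exceeds the pool after clamping", {
  sp <- treatment_spec(400)
  bg <- delta_to_atpercent(-27)
  set.seed(31)
  ap <- runif(50, bg - 0.1, 3.2)  # includes overshoots on both sides
  deriv <- (4 * ap + 2 * bg) / 6
  res <- collect_qc(glucose_derived_storage(25, deriv, rep("PHB", 50), sp, bg))
  expect_true(all(res$value >= 0 & res$value <= 25 + 1e-12))
})
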