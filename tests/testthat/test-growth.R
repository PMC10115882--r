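test_that("kit background correction recovers DNA 18O", {
  # (100 * 1.0 - 50 * 0.2005) / 50 with o_dna = 0.31 * 161.29 ~ 50
  expect_equal(kit_background_correct(50 / 0.31, 100, 1.0), 1.7995,
               tolerance = 1e-6)
  # no kit oxygen: capsule at% is DNA at%
  expect_equal(kit_background_correct(10, 3.1, 1.23), 1.23)
  # unlabelled control stays at natural abundance
  expect_equal(kit_background_correct(5, 4, 0.2005), 0.2005)
  expect_error(kit_background_correct(100, 10, 1),
               class = "sg_inconsistent_oxygen")
})

test_that("fraction of new DNA follows the 70% water two-pool model", {
  ap_new <- 0.7 * 4.2 + 0.3 * 0.2005
  expect_equal(fraction_new_dna(ap_new), 1)
  expect_equal(fraction_new_dna(0.2005), 0)
  expect_equal(fraction_new_dna(1.600325), 0.5)  # midpoint of the endmembers
  res <- collect_qc(fraction_new_dna(c(0.19, 3.2)))
  expect_equal(res$value, c(0, 1))
  expect_equal(res$qc$what, "f_new_clamped")
  expect_error(fraction_new_dna(1, ap_water = 0.2005),
               class = "sg_degenerate_label")
  expect_error(fraction_new_dna(1, f_water = 0), class = "sg_invalid_f_water")
})

test_that("error propagation follows quadrature rules", {
  s <- propagate_sum(mean_sd(10, 1, units = "u"), mean_sd(5, 1, units = "u"))
  expect_equal(s$value, 15)
  expect_equal(s$sd, sqrt(2))
  expect_equal(propagate_sum(mean_sd(1, 0), mean_sd(2, 0))$sd, 0)
  # commutativity
  s2 <- propagate_sum(mean_sd(5, 1, units = "u"), mean_sd(10, 1, units = "u"))
  expect_equal(s$value, s2$value); expect_equal(s$sd, s2$sd)
  expect_error(propagate_sum(mean_sd(1, 0, units = "a"),
                             mean_sd(1, 0, units = "b")),
               class = "sg_unit_mismatch")

  r <- propagate_ratio(mean_sd(50, 5), mean_sd(100, 10))
  expect_equal(r$value, 0.5)
  expect_equal(r$sd, 0.5 * sqrt(0.01 + 0.01))
  expect_equal(propagate_ratio(mean_sd(6, 0), mean_sd(3, 0))$sd, 0)
  expect_error(propagate_ratio(mean_sd(1, 1), mean_sd(0, 1)),
               class = "sg_degenerate_ratio")

  g <- dna_growth_c(mean_sd(0.1, 0.01), mean_sd(300, 30, units = "ug C/g"))
  expect_equal(g$value, 30)
  expect_equal(g$sd, 30 * sqrt(0.02))
  expect_equal(dna_growth_c(mean_sd(0, 0), mean_sd(300, 30))$value, 0)
  expect_error(dna_growth_c(mean_sd(0.1, 0), mean_sd(0, 0)),
               class = "sg_nonpositive_mbc")
})

test_that("propagated sds agree with a Monte-Carlo oracle at small rel sd", {
  a <- mean_sd(20, 2)   # 10% relative
  b <- mean_sd(50, 6)   # 12% relative
  # sums: first-order propagation is exact, sd-to-sd comparison is fair
  expect_equal(propagate_sum(a, b)$sd, mc_propagate(`+`, a, b),
               tolerance = 0.02)
  # products/ratios: compare on the relative-sd scale (see test-acceptance)
  mc_rel <- function(op, n = 2e5, seed = 424242) {
    set.seed(seed)
    z <- op(rnorm(n, a$value, a$sd), rnorm(n, b$value, b$sd))
    sd(z) / abs(mean(z))
  }
  r <- propagate_ratio(a, b)
  expect_lt(abs(r$sd / r$value - mc_rel(`/`)), 0.02)
  pr <- propagate_product(a, b)
  expect_lt(abs(pr$sd / pr$value - mc_rel(`*`)), 0.02)
})

test_that("growth decomposition metrics", {
  dna <- mean_sd(10, 1, units = "ug C/g")
  sto <- mean_sd(27.9, 3, units = "ug C/g")
  tot <- total_growth(dna, sto)
  expect_equal(tot$value, 37.9)
  expect_equal(tot$sd, sqrt(1 + 9))
  ex <- extra_growth_pct(sto, dna)
  expect_equal(ex$value, 279)
  expect_equal(ex$sd, 279 * sqrt((3 / 27.9)^2 + (1 / 10)^2))
  expect_equal(extra_growth_pct(dna, dna)$value, 100)
  expect_equal(extra_growth_pct(mean_sd(0, 0, units = "ug C/g"), dna)$value, 0)
  expect_error(extra_growth_pct(sto, mean_sd(0, 1)),
               class = "sg_nonpositive_growth")
})

test_that("storage:MBC ratio is formed per sample", {
  r <- storage_to_mbc_ratio(c(10, 15), c(10, 15), c(100, 100))
  expect_equal(r$value, 0.25)
  expect_equal(r$sd, sd(c(0.2, 0.3)))
  # identical per-sample ratios -> sd 0; scaling invariance
  r2 <- storage_to_mbc_ratio(c(5, 10), c(5, 10), c(40, 80))
  expect_equal(r2$value, 0.25); expect_equal(r2$sd, 0)
  res <- collect_qc(storage_to_mbc_ratio(c(1, 1), c(1, 1), c(10, -5)))
  expect_equal(res$value$n, 1L)
  expect_true("ratio_sample_dropped" %in% res$qc$what)
})

test_that("endurance hours scale linearly with stored C", {
  expect_equal(endurance_hours(35, 0.1), 350)
  expect_equal(endurance_hours(0, 0.2), 0)
  expect_equal(endurance_hours(44, 0.2), 2 * endurance_hours(22, 0.2))
  expect_error(endurance_hours(10, 0), class = "sg_nonpositive_rate")
})

test_that("summarize_treatment uses the sample sd", {
  s <- summarize_treatment(c(1, 2, 3), units = "u")
  expect_equal(s$value, 2); expect_equal(s$sd, 1); expect_equal(s$n, 3L)
  expect_equal(summarize_treatment(c(3, 1, 2))$value, 2)  # order-invariant
  res <- collect_qc(summarize_treatment(7))
  expect_equal(res$value$sd, 0)
  expect_equal(res$qc$what, "singleton_treatment")
  expect_error(summarize_treatment(numeric()), class = "sg_empty_group")
})
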