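test_that("reference scenario is valid and encodes the design", {
  cfg <- default_paper_scenario()
  tr <- cfg$treatments
  expect_equal(nrow(tr), 12)  # 3 C levels x 2 nutrient levels x 2 timepoints
  expect_setequal(unique(tr$glucose_c), c(0, 90, 400))
  expect_setequal(unique(tr$timepoint_h), c(24, 96))
  expect_equal(cfg$n_reps, 4L)
  # zero-C treatments carry no glucose-derived fractions
  z <- tr[tr$glucose_c == 0, ]
  expect_true(all(z[c("gf_mbc", "gf_phb", "gf_tag", "gf_doc")] == 0))
  # surplus-mode PHB: high-C no-nutrient exceeds high-C nutrient at 96 h
  expect_gt(tr$true_phb_c[tr$glucose_c == 400 & !tr$nutrients &
                            tr$timepoint_h == 96],
            tr$true_phb_c[tr$glucose_c == 400 & tr$nutrients &
                            tr$timepoint_h == 96])
  # mass balance holds (construction would have errored otherwise)
  bal <- mass_balance(cfg)
  expect_true(all(bal$glucose_recovered <= bal$glucose_c + 1e-9 |
                    bal$glucose_c == 0))
})

test_that("config validation rejects broken scenarios", {
  cfg <- default_paper_scenario()
  tr <- cfg$treatments
  tr$gf_phb[tr$glucose_c == 0] <- 0.2
  expect_error(scenario_config(tr, cfg$gas), class = "sg_invalid_config")
  tr <- cfg$treatments
  tr$gf_doc[5] <- 1.5
  expect_error(scenario_config(tr, cfg$gas), class = "sg_invalid_config")
  tr <- cfg$treatments
  tr$true_mbc <- tr$true_mbc * 50  # glucose-derived pools exceed the dose
  expect_error(scenario_config(tr, cfg$gas), class = "sg_mass_balance")
  expect_error(scenario_config(tr[-(1:nrow(tr)), -1], cfg$gas),
               class = "sg_schema_error")
})

test_that("generation is deterministic and matches the configured shape", {
  cfg <- default_paper_scenario()
  m1 <- generate_experiment(cfg, seed = 5)
  m2 <- generate_experiment(cfg, seed = 5)
  expect_identical(m1, m2)
  m3 <- generate_experiment(cfg, seed = 6)
  expect_false(identical(m1$cfe, m3$cfe))
  expect_error(generate_experiment(cfg), class = "sg_seed_required")
  # replicate counts, labels, timepoints exactly as configured
  expect_equal(nrow(m1$cfe), 12 * 4)
  expect_equal(nrow(m1$dna), 12 * 4)
  expect_equal(nrow(m1$storage), 12 * 4 * 4)  # PHB + 3 fatty acids
  expect_setequal(unique(m1$cfe$treatment),
                  c("C0", "C0+ntr", "C90", "C90+ntr", "C400", "C400+ntr"))
  expect_equal(as.integer(table(m1$cfe$treatment)), rep(8L, 6))
})

test_that("generated isotope values stay below their labelled endmembers", {
  ms <- generate_experiment(default_paper_scenario(), seed = 12)
  expect_true(all(delta_to_atpercent(ms$gas$delta13c) <= 3))
  expect_true(all(ms$storage$ap13c_derivative <= 3))
  ap_new <- 0.7 * 4.2 + 0.3 * 0.2005
  expect_true(all(ms$dna$ap18o_measured <= ap_new))
  # capsule O always contains at least the DNA oxygen
  expect_true(all(ms$dna$o_total >= 0.31 * ms$dna$dna_mass))
})

test_that("fungal hotspot injector spikes one 24 h fungal fatty acid", {
  base <- generate_experiment(default_paper_scenario(), seed = 9)
  hot <- generate_experiment(default_paper_scenario(fungal_hotspot = TRUE),
                             seed = 9)
  d <- hot$storage$amount / base$storage$amount
  changed <- which(abs(d - 1) > 1e-12)
  expect_equal(length(changed), 1L)
  expect_equal(hot$storage$compound[changed], "18:2w6")
  expect_equal(hot$storage$timepoint_h[changed], 24)
  expect_equal(d[changed], 10)
})

test_that("nutrient dose arithmetic from C:N:P and CUE", {
  d <- compute_nutrient_dose(400, cue = 0.5)
  expect_equal(d$n_ug, 400 * 0.5 * 5 / 38)
  expect_equal(round(d$n_umol, 3), 1.879)
  expect_equal(round(d$p_umol, 3), 0.170)
  # linear in the C dose
  expect_equal(compute_nutrient_dose(200)$n_ug, d$n_ug / 2)
  expect_error(compute_nutrient_dose(400, cue = 0),
               class = "sg_invalid_config")
})
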