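test_that("uptake rate follows the radiocarbon formula with 1.06 fractionation", {
  s <- tracer_incubation("Fe(II)", TRUE, c14_fixed = 100,
                         total_activity = 10000, dic = 24000, duration_h = 4)
  expect_equal(uptake_rate(s)$value, 0.01 * 24000 * 1.06 / 4)  # 63.6

  zero <- tracer_incubation("Fe(II)", TRUE, 0, 10000, 24000, 4)
  expect_equal(uptake_rate(zero)$value, 0)

  # degree-1 homogeneity in counts and DIC, inverse in duration
  dbl <- tracer_incubation("Fe(II)", TRUE, 200, 10000, 24000, 4)
  expect_equal(uptake_rate(dbl)$value, 2 * uptake_rate(s)$value)
  dic2 <- tracer_incubation("Fe(II)", TRUE, 100, 10000, 48000, 4)
  expect_equal(uptake_rate(dic2)$value, 2 * uptake_rate(s)$value)
  t2 <- tracer_incubation("Fe(II)", TRUE, 100, 10000, 24000, 8)
  expect_equal(uptake_rate(t2)$value, uptake_rate(s)$value / 2)

  expect_error(tracer_incubation("x", TRUE, 1, 0, 24000, 4), "positive")
  expect_error(tracer_incubation("x", TRUE, 1, 1, 24000, 0), "positive")
  expect_error(tracer_incubation("x", TRUE, -1, 1, 24000, 4), "non-negative")
})

test_that("net photosynthetic uptake subtracts dark from light and flags negatives", {
  mk <- function(v, light) {
    # invert the formula so uptake_rate() returns exactly v
    uptake_rate(tracer_incubation("Fe(II)+DCMU", light,
                                  c14_fixed = v * 1e6 * 4 / (24000 * 1.06),
                                  total_activity = 1e6, dic = 24000,
                                  duration_h = 4))
  }
  net <- net_photosynthetic_uptake(mk(2.08, TRUE), mk(0.72, FALSE))
  expect_equal(net$value, 1.36, tolerance = 1e-12)
  expect_true(net$net)
  expect_false(net$negative)

  same <- net_photosynthetic_uptake(mk(0.9, TRUE), mk(0.9, FALSE))
  expect_equal(same$value, 0)

  neg <- net_photosynthetic_uptake(mk(0.5, TRUE), mk(0.9, FALSE))
  expect_equal(neg$value, -0.4, tolerance = 1e-12)
  expect_true(neg$negative)

  other <- uptake_rate(tracer_incubation("No addition", FALSE, 1, 1e6, 24000, 4))
  expect_error(net_photosynthetic_uptake(mk(1, TRUE), other), "mismatch")
})

test_that("stoichiometric conversion of carbon uptake reproduces the tracer-based rate", {
  r <- fe_oxidation_from_carbon(1.36, 0.72, ratio = 4,
                                illuminated_hours_per_day = 12)
  expect_equal(r$value, 2.56, tolerance = 0.01)
  expect_identical(r$method, "tracer")
  # both conventional molar masses agree at reporting precision
  expect_equal(fe_oxidation_from_carbon(1.36, 0.72, 4, 12,
                                        molar_mass_c = 12.0)$value,
               2.56, tolerance = 0.01)

  expect_equal(fe_oxidation_from_carbon(1.0, 1.0, 4, 12)$value, 0)
  expect_true(attr(fe_oxidation_from_carbon(0.5, 0.9, 4, 12), "nonpositive"))
  expect_equal(fe_oxidation_from_carbon(1.0, 0, 4, 24, molar_mass_c = 12)$value,
               8.0, tolerance = 1e-12)

  # linear in the carbon-rate difference and in the ratio
  expect_equal(fe_oxidation_from_carbon(2.72, 1.44, 4, 12)$value,
               2 * fe_oxidation_from_carbon(1.36, 0.72, 4, 12)$value)
  expect_equal(fe_oxidation_from_carbon(1.36, 0.72, 8, 12)$value,
               2 * fe_oxidation_from_carbon(1.36, 0.72, 4, 12)$value)
  expect_error(fe_oxidation_from_carbon(1, 0, 0, 12), "positive")
  expect_error(fe_oxidation_from_carbon(1, 0, 4, 25), "24")
})

test_that("treatment summaries report unbiased SD and light-dark nets", {
  mk <- function(v, light, treatment = "Fe(II)+DCMU")
    tracer_incubation(treatment, light,
                      c14_fixed = v * 1e6 * 4 / (24000 * 1.06),
                      total_activity = 1e6, dic = 24000, duration_h = 4,
                      dcmu = TRUE)
  out <- treatment_summary(list(mk(1.0, TRUE), mk(2.0, TRUE),
                                mk(0.7, FALSE), mk(0.7, FALSE),
                                mk(0.4, TRUE, "No addition+DCMU")))
  light_row <- out$groups[out$groups$light & out$groups$treatment == "Fe(II)+DCMU", ]
  expect_equal(light_row$mean, 1.5, tolerance = 1e-12)
  expect_equal(light_row$sd, sqrt(0.5), tolerance = 1e-10)  # ~0.7071
  dark_row <- out$groups[!out$groups$light, ]
  expect_equal(dark_row$sd, 0)
  single <- out$groups[out$groups$treatment == "No addition+DCMU", ]
  expect_true(is.na(single$sd))
  net <- out$net[out$net$treatment == "Fe(II)+DCMU", ]
  expect_equal(net$net, 0.8, tolerance = 1e-12)
  expect_error(treatment_summary(list()), "no samples")
})

test_that("mean recovered uptake over many noisy replicates is unbiased", {
  true_uptake <- 1.36
  reps <- generate_tracer(true_uptake, noise_cv = 0.2, n_replicates = 1000,
                          seed = 7L)
  rates <- vapply(reps, function(s) uptake_rate(s)$value, 0)
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - true_uptake), 3 * se)
})
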