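test_that("profile generation matches its configured structure at zero noise", {
  sc <- profile_scenario(noise_sd = 0,
                         depths = c(seq(0, 11.5, 0.5), 11.8, seq(12, 20, 0.5)))
  prof <- generate_profiles(sc)
  expect_named(prof, c("O2", "FeII", "FeIII"))

  # mixolimnion oxic (~238 uM), monimolimnion anoxic
  o2 <- prof$O2
  expect_equal(o2$value[o2$depth_m == 0], 238, tolerance = 1e-4)
  expect_lt(o2$value[o2$depth_m == 20], 1e-10)
  # half the surface value exactly at the chemocline
  expect_equal(o2$value[o2$depth_m == 11.8], 238 / 2, tolerance = 1e-10)

  # Fe(II): zero above the gradient window, configured value at its bottom
  feII <- prof$FeII
  expect_true(all(feII$value[feII$depth_m <= 15] == 0))
  expect_equal(feII$value[feII$depth_m == 18], 230, tolerance = 1e-10)

  # Fe(III): peak heights at peak centers; no peaks -> identically zero
  feIII <- prof$FeIII
  for (p in sc$feIII_peaks) {
    at <- which.min(abs(feIII$depth_m - p[1]))
    expect_equal(feIII$value[at], p[3], tolerance = 0.05)
  }
  none <- generate_profiles(profile_scenario(feIII_peaks = list(), noise_sd = 0))
  expect_true(all(none$FeIII$value == 0))
})

test_that("noise-free profiles return the configured gradient exactly", {
  sc <- profile_scenario(feII_bottom = 212.1, noise_sd = 0)
  expect_equal(scenario_true_gradient(sc), 7.07e-4, tolerance = 1e-15)
  g <- linear_gradient(generate_profiles(sc)$FeII, 15, 18)
  expect_equal(g$slope, scenario_true_gradient(sc), tolerance = 1e-10)
})

test_that("generators are bit-reproducible functions of their seed", {
  sc <- profile_scenario(noise_sd = 3, seed = 11L)
  expect_identical(generate_profiles(sc), generate_profiles(sc))
  sc2 <- profile_scenario(noise_sd = 3, seed = 12L)
  expect_false(identical(generate_profiles(sc)$FeII$value,
                         generate_profiles(sc2)$FeII$value))

  isc <- incubation_scenario(noise_sd = 5, seed = 11L)
  expect_identical(generate_incubation(isc), generate_incubation(isc))

  expect_identical(generate_tracer(1.36, noise_cv = 0.2, n_replicates = 2,
                                   seed = 11L),
                   generate_tracer(1.36, noise_cv = 0.2, n_replicates = 2,
                                   seed = 11L))

  # the global random state is left untouched
  set.seed(99)
  before <- .Random.seed
  invisible(generate_profiles(sc))
  invisible(generate_incubation(isc))
  expect_identical(.Random.seed, before)
})

test_that("incubation truth conserves iron mass and recovers the light rate", {
  sc <- incubation_scenario(true_light_rate = 2.65, dark_rate = 0,
                            initial_feII = 500, duration_h = 120,
                            noise_sd = 0)
  s <- generate_incubation(sc)
  expect_equal(s$feII + s$feIII, rep(500, nrow(s)), tolerance = 1e-10)
  expect_equal(light_phase_rate(s)$value, 2.65, tolerance = 1e-10)
  # dark-phase loss contributes to the series but not the light-phase x-axis
  both <- generate_incubation(incubation_scenario(true_light_rate = 2,
                                                  dark_rate = 0,
                                                  noise_sd = 0))
  expect_equal(light_phase_rate(both)$value, 2, tolerance = 1e-10)
})

test_that("tracer generation inverts the uptake formula", {
  s <- generate_tracer(63.6, dic = 24000, total_activity = 1e6,
                       duration_h = 4, noise_cv = 0)[[1]]
  expect_equal(uptake_rate(s)$value, 63.6, tolerance = 1e-10)
  zero <- generate_tracer(0, noise_cv = 0.3, n_replicates = 3, seed = 1L)
  expect_true(all(vapply(zero, `[[`, 0, "c14_fixed") == 0))
})

test_that("noisy profile gradients are unbiased over seeded replicates", {
  sc0 <- profile_scenario(feII_bottom = 212.1)
  truth <- scenario_true_gradient(sc0)
  est <- vapply(seq_len(200), function(i) {
    sc <- profile_scenario(feII_bottom = 212.1, noise_sd = 2, seed = i)
    linear_gradient(generate_profiles(sc)$FeII, 15, 18)$slope
  }, 0)
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se)
})
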