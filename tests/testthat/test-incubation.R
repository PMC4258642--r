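test_that("window rate uses endpoint concentrations and reports oxidation positive", {
  s <- incubation_series(c(0, 7, 60), c(10500, 10000, 4700), time_unit = "d",
                         condition = "light")
  r <- window_rate(s, 7, 60)
  expect_equal(r$value, 5300 / 53)   # 100 umol l-1 d-1
  expect_identical(r$unit, "umol/l/d")
  expect_false(r$negative)

  flat <- incubation_series(c(0, 10, 20), c(500, 500, 500), time_unit = "h")
  expect_equal(window_rate(flat, 0, 20)$value, 0)

  rising <- incubation_series(c(0, 10), c(100, 200), time_unit = "h")
  rr <- window_rate(rising, 0, 10)
  expect_true(rr$negative)
  expect_equal(rr$value, -10)

  # shift invariance
  shifted <- incubation_series(c(0, 7, 60), c(10500, 10000, 4700) + 250,
                               time_unit = "d")
  expect_equal(window_rate(shifted, 7, 60)$value, r$value)

  # interpolated endpoints between bracketing observations
  mid <- window_rate(s, 7, 33.5)   # midpoint of the 7-60 segment
  expect_equal(mid$value, r$value, tolerance = 1e-12)

  expect_error(window_rate(s, 60, 7), "t0")
  expect_error(window_rate(s, 0, 70), "outside")
})

test_that("killed-control correction subtracts the control's drift", {
  live <- incubation_series(c(0, 12, 24), c(500, 450, 400), time_unit = "h")
  flat_ctrl <- incubation_series(c(0, 12, 24), c(480, 480, 480),
                                 time_unit = "h", condition = "killed",
                                 killed = TRUE)
  same <- killed_control_correct(live, flat_ctrl)
  expect_equal(same$feII, live$feII)
  expect_true(attr(same, "corrected"))

  drifting <- incubation_series(c(0, 24), c(480, 470), time_unit = "h",
                                condition = "killed", killed = TRUE)
  corr <- killed_control_correct(live, drifting)
  expect_equal(corr$feII, c(500, 455, 410))  # -10 drift over 24 h removed

  # correction then window rate == window rate of pointwise differences
  ctrl2 <- incubation_series(c(0, 12, 24), c(480, 473, 462), time_unit = "h",
                             condition = "killed", killed = TRUE)
  corr2 <- killed_control_correct(live, ctrl2)
  diffs <- incubation_series(c(0, 12, 24),
                             live$feII - (ctrl2$feII - ctrl2$feII[1]),
                             time_unit = "h")
  expect_equal(window_rate(corr2, 0, 24)$value,
               window_rate(diffs, 0, 24)$value, tolerance = 1e-12)

  expect_error(killed_control_correct(live, live), "killed")
  short <- incubation_series(c(0, 12), c(480, 480), time_unit = "h",
                             killed = TRUE)
  expect_error(killed_control_correct(live, short), "support")
})

test_that("light-phase regression recovers a schedule-dependent loss rate", {
  # loses exactly 2.65 uM per illuminated hour, flat in the dark
  s <- generate_incubation(incubation_scenario(true_light_rate = 2.65,
                                               dark_rate = 0, noise_sd = 0))
  r <- light_phase_rate(s)
  expect_equal(r$value, 2.65, tolerance = 1e-10)
  expect_identical(r$unit, "umol/l/h")

  # noiseless 1 uM per lit hour over 48 h (24 h illuminated)
  s1 <- generate_incubation(incubation_scenario(true_light_rate = 1,
                                                duration_h = 48,
                                                sampling_interval_h = 3,
                                                noise_sd = 0))
  expect_equal(light_phase_rate(s1)$value, 1.0, tolerance = 1e-10)

  dark_only <- incubation_series(c(13, 15, 20), c(500, 499, 498),
                                 time_unit = "h", illuminated_hours = 12)
  expect_error(light_phase_rate(dark_only), "illuminated")

  no_sched <- incubation_series(c(0, 6), c(500, 480), time_unit = "h")
  expect_error(light_phase_rate(no_sched), "schedule")
})

test_that("light-phase estimates are unbiased across noisy replicates", {
  for (true_rate in c(0.5, 2.65, 10)) {
    est <- vapply(seq_len(200), function(i) {
      sc <- incubation_scenario(true_light_rate = true_rate, dark_rate = 0,
                                initial_feII = 2000, duration_h = 120,
                                sampling_interval_h = 6, noise_sd = 5,
                                seed = i)
      light_phase_rate(generate_incubation(sc))$value
    }, 0)
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - true_rate), 3 * se + 1e-9)
  }
})

test_that("hourly rates scale to daily rates only by an explicit hour count", {
  expect_equal(daily_rate(2.65, 24), 63.6)
  expect_equal(daily_rate(2.65, 12), 31.8)
  expect_error(daily_rate(2.65, 0), "0, 24")
  expect_error(daily_rate(2.65, 25), "0, 24")
})

test_that("incubation CSV round-trips through the reader", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,unit,feII_uM,feIII_uM,condition",
               "0,h,500,0,light+DCMU",
               "12,h,468.2,31.8,light+DCMU",
               "24,h,468.2,31.8,light+DCMU"), f)
  s <- read_incubation(f, illuminated_hours = 12)
  expect_s3_class(s, "incubation_series")
  expect_equal(s$feII, c(500, 468.2, 468.2))
  expect_equal(attr(s, "illuminated_hours"), 12)
  expect_identical(attr(s, "time_unit"), "h")
})
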