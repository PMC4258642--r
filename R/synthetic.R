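# Seeded synthetic-data generators with known ground truth for every
# pipeline stage: stratified water-column profiles, light/dark incubation
# series, and 14C tracer records. Each generator uses one local random
# stream derived from its explicit seed; the global random state is left
# untouched.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scenario for a stratified water-column profile set
#'
#' Defaults describe the study conditions: an oxic mixolimnion of ~238 uM
#' O2 collapsing at the chemocline, an anoxic Fe(II)-rich monimolimnion
#' reaching ~230 uM at depth, and two small Fe(III) peaks near the
#' chemocline (~2.8 uM around 10.9 m and ~2.0 uM around 12.5 m).
#'
#' @param chemocline_depth chemocline depth in m.
#' @param chemocline_width width of the O2 transition in m.
#' @param o2_mixolimnion surface-layer O2 in uM.
#' @param feII_bottom Fe(II) reached at the bottom of the gradient window,
#'   uM; together with the window this sets the true linear slope.
#' @param feIII_peaks list of `c(center_m, width_m, height_uM)` Gaussian
#'   peaks.
#' @param gradient_window `c(z_top, z_bottom)` in m; Fe(II) is 0 above the
#'   window top and rises linearly to `feII_bottom` at the window bottom.
#' @param noise_sd Gaussian observation noise SD in uM.
#' @param depths sampling depths in m.
#' @param seed integer seed.
#' @return A `profile_scenario` list.
#' @export
profile_scenario <- function(chemocline_depth = 11.8, chemocline_width = 1.0,
                             o2_mixolimnion = 238, feII_bottom = 230,
                             feIII_peaks = list(c(10.9, 0.6, 2.8),
                                                c(12.5, 0.4, 2.0)),
                             gradient_window = c(15, 18), noise_sd = 0,
                             depths = seq(0, 20, by = 0.25), seed = 1L) {
  stopifnot(chemocline_width > 0, o2_mixolimnion >= 0, feII_bottom >= 0,
            noise_sd >= 0, gradient_window[1] < gradient_window[2])
  for (p in feIII_peaks) stopifnot(length(p) == 3L, p[2] > 0, p[3] >= 0)
  structure(list(chemocline_depth = chemocline_depth,
                 chemocline_width = chemocline_width,
                 o2_mixolimnion = o2_mixolimnion, feII_bottom = feII_bottom,
                 feIII_peaks = feIII_peaks, gradient_window = gradient_window,
                 noise_sd = noise_sd, depths = depths, seed = as.integer(seed)),
            class = "profile_scenario")
}

#' True Fe(II) gradient implied by a profile scenario
#'
#' @param sc a [profile_scenario()].
#' @return Slope in umol cm-4 (uM per m x 1e-5).
#' @export
scenario_true_gradient <- function(sc) {
  span_m <- sc$gradient_window[2] - sc$gradient_window[1]
  sc$feII_bottom / span_m * 1e-5
}

#' Generate a synthetic stratified profile set
#'
#' O2 follows a logistic collapse at the chemocline (scale = width / 4, so
#' the transition is ~98% complete across the stated width); Fe(II) is 0
#' above the gradient-window top and rises linearly to `feII_bottom` at the
#' window bottom, continuing below; Fe(III) is a sum of Gaussian peaks.
#' Seeded Gaussian noise is added to each observation; the same seed gives
#' an identical output.
#'
#' @param sc a [profile_scenario()].
#' @return Named list of three [depth_profile()]s: `O2`, `FeII`, `FeIII`
#'   (all in uM).
#' @export
generate_profiles <- function(sc) {
  stopifnot(inherits(sc, "profile_scenario"))
  z <- sc$depths
  scale <- sc$chemocline_width / 4
  o2 <- sc$o2_mixolimnion / (1 + exp((z - sc$chemocline_depth) / scale))
  w <- sc$gradient_window
  slope_uM_m <- sc$feII_bottom / (w[2] - w[1])
  feII <- pmax(0, (z - w[1]) * slope_uM_m)
  feIII <- rep(0, length(z))
  for (p in sc$feIII_peaks)
    feIII <- feIII + p[3] * exp(-(z - p[1])^2 / (2 * p[2]^2))
  if (sc$noise_sd > 0) {
    noise <- with_local_seed(sc$seed,
                             matrix(stats::rnorm(3 * length(z), 0, sc$noise_sd),
                                    ncol = 3))
    o2 <- o2 + noise[, 1]; feII <- feII + noise[, 2]; feIII <- feIII + noise[, 3]
  }
  list(O2 = depth_profile("O2", z, o2, "uM"),
       FeII = depth_profile("FeII", z, feII, "uM"),
       FeIII = depth_profile("FeIII", z, feIII, "uM"))
}

#' Scenario for a light/dark bottle-incubation series
#'
#' Defaults emulate the ex-situ experiment: ~500 uM Fe(II) amendment, a
#' 12 h light / 12 h dark cycle, 120 h duration.
#'
#' @param true_light_rate Fe(II) loss rate during illuminated phases,
#'   umol l-1 h-1.
#' @param dark_rate Fe(II) loss rate in the dark, umol l-1 h-1.
#' @param initial_feII starting Fe(II), uM.
#' @param illuminated_hours illuminated hours per 24 h cycle (light first).
#' @param duration_h run length, h.
#' @param sampling_interval_h sampling interval, h.
#' @param noise_sd Gaussian observation noise SD, uM.
#' @param condition condition label.
#' @param killed logical, generate as a killed control?
#' @param seed integer seed.
#' @return An `incubation_scenario` list.
#' @export
incubation_scenario <- function(true_light_rate = 2.65, dark_rate = 0,
                                initial_feII = 500, illuminated_hours = 12,
                                duration_h = 120, sampling_interval_h = 6,
                                noise_sd = 0, condition = "light+DCMU",
                                killed = FALSE, seed = 1L) {
  stopifnot(true_light_rate >= 0, dark_rate >= 0, initial_feII >= 0,
            illuminated_hours > 0, illuminated_hours <= 24,
            duration_h > 0, sampling_interval_h > 0, noise_sd >= 0)
  structure(list(true_light_rate = true_light_rate, dark_rate = dark_rate,
                 initial_feII = initial_feII,
                 illuminated_hours = illuminated_hours,
                 duration_h = duration_h,
                 sampling_interval_h = sampling_interval_h,
                 noise_sd = noise_sd, condition = condition,
                 killed = isTRUE(killed), seed = as.integer(seed)),
            class = "incubation_scenario")
}

#' Generate a synthetic incubation series
#'
#' The true Fe(II) signal declines at `true_light_rate` during illuminated
#' phases and `dark_rate` otherwise, floored at zero; Fe(III) mirrors the
#' loss exactly (mass balance holds in the truth signal before noise).
#' Seeded Gaussian noise is then added to both observed series and the
#' observations are floored at zero.
#'
#' @param sc an [incubation_scenario()].
#' @return An [incubation_series()] on the hours scale, carrying the
#'   scenario's illumination schedule.
#' @export
generate_incubation <- function(sc) {
  stopifnot(inherits(sc, "incubation_scenario"))
  t <- seq(0, sc$duration_h, by = sc$sampling_interval_h)
  lit <- cumulative_light_h(t, sc$illuminated_hours)
  truth <- pmax(0, sc$initial_feII - sc$true_light_rate * lit -
                  sc$dark_rate * (t - lit))
  feIII_truth <- sc$initial_feII - truth
  feII <- truth; feIII <- feIII_truth
  if (sc$noise_sd > 0) {
    noise <- with_local_seed(sc$seed,
                             matrix(stats::rnorm(2 * length(t), 0, sc$noise_sd),
                                    ncol = 2))
    feII <- pmax(0, truth + noise[, 1])
    feIII <- pmax(0, feIII_truth + noise[, 2])
  }
  incubation_series(t, feII, feIII, time_unit = "h",
                    condition = sc$condition,
                    illuminated_hours = sc$illuminated_hours,
                    killed = sc$killed)
}

#' Generate synthetic 14C tracer incubation records
#'
#' Inverts the uptake-rate formula: the filter counts implied by a true
#' uptake rate are `true_uptake x total_activity x duration / (dic x
#' 1.06)`, perturbed by multiplicative lognormal noise with unit mean and
#' the given coefficient of variation.
#'
#' @param true_uptake true carbon-uptake rate, ug C l-1 h-1.
#' @param dic dissolved inorganic carbon, ug C l-1.
#' @param total_activity total label per vial (counts).
#' @param duration_h incubation duration, h.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates number of replicate records.
#' @param treatment treatment label.
#' @param light logical, light incubation?
#' @param dcmu logical, PSII inhibitor added?
#' @param seed integer seed.
#' @return List of [tracer_incubation()]s.
#' @export
generate_tracer <- function(true_uptake, dic = 24000, total_activity = 1e6,
                            duration_h = 4, noise_cv = 0, n_replicates = 1,
                            treatment = "Fe(II)+DCMU", light = TRUE,
                            dcmu = TRUE, seed = 1L) {
  stopifnot(true_uptake >= 0, dic > 0, total_activity > 0, duration_h > 0,
            noise_cv >= 0, n_replicates >= 1)
  base <- true_uptake * total_activity * duration_h / (dic * C14_FRACTIONATION)
  mult <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    with_local_seed(seed,
                    stats::rlnorm(n_replicates, meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog))
  } else rep(1, n_replicates)
  lapply(mult, function(m)
    tracer_incubation(treatment, light, c14_fixed = base * m,
                      total_activity = total_activity, dic = dic,
                      duration_h = duration_h, dcmu = dcmu))
}
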