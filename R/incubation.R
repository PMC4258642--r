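# Fe(II)-oxidation rates from bottle-incubation time series: window rates
# between sampling days, light-phase regression rates under a light/dark
# schedule, and killed-control correction for abiotic signal.

#' Construct an incubation time series
#'
#' @param time numeric observation times, strictly increasing.
#' @param feII Fe(II) concentrations in uM, non-negative.
#' @param feIII optional Fe(III) concentrations in uM.
#' @param time_unit `"h"` or `"d"`; no implicit conversion is ever applied.
#' @param condition free-text condition label (light/dark, +-DCMU, killed).
#' @param illuminated_hours illuminated hours per 24 h cycle (used by
#'   [light_phase_rate()]); `NA` when the schedule is not relevant. The
#'   cycle starts with the illuminated phase at time 0 (hours scale).
#' @param killed logical, is this a killed control?
#' @return An `incubation_series` data frame with attributes.
#' @export
incubation_series <- function(time, feII, feIII = NULL, time_unit = c("h", "d"),
                              condition = "light", illuminated_hours = NA_real_,
                              killed = FALSE) {
  time_unit <- match.arg(time_unit)
  if (length(time) != length(feII))
    stop("time and feII lengths differ", call. = FALSE)
  if (length(time) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(feII < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (!is.null(feIII) && (length(feIII) != length(time) || any(feIII < 0)))
    stop("feIII must match time and be non-negative", call. = FALSE)
  df <- data.frame(time = time, feII = feII)
  if (!is.null(feIII)) df$feIII <- feIII
  structure(df, time_unit = time_unit, condition = condition,
            illuminated_hours = illuminated_hours, killed = isTRUE(killed),
            class = c("incubation_series", "data.frame"))
}

#' @export
print.incubation_series <- function(x, ...) {
  cat("<incubation_series> ", attr(x, "condition"),
      if (attr(x, "killed")) " (killed control)",
      ", ", nrow(x), " points over ", max(x$time) - min(x$time), " ",
      attr(x, "time_unit"),
      if (is.finite(attr(x, "illuminated_hours")))
        paste0(", ", attr(x, "illuminated_hours"), " h light per 24 h"),
      "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read an incubation series from a CSV file
#'
#' Header `time,unit,feII_uM,feIII_uM,condition`; the light schedule is
#' passed separately (sidecar configuration), not stored per row.
#'
#' @param path file path.
#' @param illuminated_hours illuminated hours per 24 h cycle.
#' @param killed logical, killed control?
#' @return An [incubation_series()].
#' @export
read_incubation <- function(path, illuminated_hours = NA_real_, killed = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "unit", "feII_uM", "condition")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("series table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unit <- unique(tab$unit)
  if (length(unit) != 1L) stop("mixed time units in one series", call. = FALSE)
  incubation_series(tab$time, tab$feII_uM,
                    feIII = if ("feIII_uM" %in% names(tab)) tab$feIII_uM,
                    time_unit = unit, condition = tab$condition[1],
                    illuminated_hours = illuminated_hours, killed = killed)
}

# Fe(II) at time t, exact at observed points, linearly interpolated between
feII_at <- function(s, t) {
  if (t < min(s$time) || t > max(s$time))
    stop("time ", t, " outside observed range [", min(s$time), ", ",
         max(s$time), "]", call. = FALSE)
  stats::approx(s$time, s$feII, xout = t, ties = "ordered")$y
}

#' Average Fe(II)-oxidation rate over a time window
#'
#' Rate = (Fe(II) at t0 - Fe(II) at t1) / (t1 - t0): positive for net
#' oxidation (Fe(II) loss), negative for net reduction. Endpoints use the
#' observed concentrations when t0/t1 are sampling times, otherwise linear
#' interpolation between the bracketing observations. Phase boundaries
#' (e.g. the end of an initial Fe(III)-reduction phase) are the caller's
#' choice of window; nothing is auto-detected.
#'
#' @param s an [incubation_series()].
#' @param t0,t1 window bounds in the series' time unit, `t0 < t1`, inside
#'   the observed range.
#' @return A `rate_estimate`: list with `value` (umol l-1 per time unit),
#'   `unit`, `window`, `method = "window"`, `corrected` (killed-control
#'   subtracted upstream?) and `negative` flag.
#' @examples
#' s <- incubation_series(c(0, 7, 60), c(10500, 10000, 4700), time_unit = "d")
#' window_rate(s, 7, 60)$value   # 100 umol l-1 d-1
#' @export
window_rate <- function(s, t0, t1) {
  stopifnot(inherits(s, "incubation_series"))
  if (!(t0 < t1)) stop("t0 must be < t1", call. = FALSE)
  v <- (feII_at(s, t0) - feII_at(s, t1)) / (t1 - t0)
  structure(list(value = v,
                 unit = paste0("umol/l/", attr(s, "time_unit")),
                 window = c(t0 = t0, t1 = t1), method = "window",
                 corrected = isTRUE(attr(s, "corrected")),
                 negative = v < 0),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate> ", format(x$value, digits = 4), " ", x$unit,
      " [", x$method,
      if (!is.null(x$window)) paste0("; window ", x$window[1], "-", x$window[2]),
      if (isTRUE(x$corrected)) "; killed-control corrected",
      "]", if (isTRUE(x$negative)) " [net reduction]", "\n", sep = "")
  invisible(x)
}

#' Subtract the killed-control drift from a live series
#'
#' The control's concentration change relative to its own start is
#' interpolated at the live series' times and subtracted, removing abiotic
#' (e.g. photochemical) Fe(II) loss or gain from the live signal.
#'
#' @param s live [incubation_series()].
#' @param control killed-control [incubation_series()] (`killed = TRUE`),
#'   same time unit, overlapping time support.
#' @return The corrected `incubation_series` (attribute `corrected` set).
#' @export
killed_control_correct <- function(s, control) {
  stopifnot(inherits(s, "incubation_series"), inherits(control, "incubation_series"))
  if (!attr(control, "killed"))
    stop("control series is not flagged as killed", call. = FALSE)
  if (!identical(attr(s, "time_unit"), attr(control, "time_unit")))
    stop("time units differ between live and control series", call. = FALSE)
  if (min(s$time) < min(control$time) || max(s$time) > max(control$time))
    stop("control does not cover the live series' time support", call. = FALSE)
  drift <- stats::approx(control$time, control$feII - control$feII[1],
                         xout = s$time, ties = "ordered")$y
  out <- s
  out$feII <- s$feII - drift
  attr(out, "corrected") <- TRUE
  out
}

# cumulative illuminated time (h) since t = 0 under an L h light /
# (24 - L) h dark cycle starting with light
cumulative_light_h <- function(t_h, illuminated_hours) {
  full <- floor(t_h / 24)
  full * illuminated_hours + pmin(t_h - full * 24, illuminated_hours)
}

#' Light-phase Fe(II)-oxidation rate under a light/dark schedule
#'
#' Least-squares slope of Fe(II) against cumulative illuminated time,
#' using only observations inside (or on the boundary of) illuminated
#' phases, sign-flipped so that oxidation is positive. The series must be
#' on the hours scale and carry its illumination schedule; the cycle
#' starts illuminated at t = 0.
#'
#' @param s an [incubation_series()] with `time_unit = "h"` and a finite
#'   `illuminated_hours` attribute.
#' @return A `rate_estimate` in umol l-1 h-1, method `"regression"`.
#' @export
light_phase_rate <- function(s) {
  stopifnot(inherits(s, "incubation_series"))
  L <- attr(s, "illuminated_hours")
  if (!is.finite(L) || L <= 0 || L > 24)
    stop("series needs an illumination schedule in (0, 24] h per cycle",
         call. = FALSE)
  if (!identical(attr(s, "time_unit"), "h"))
    stop("light_phase_rate expects a series on the hours scale", call. = FALSE)
  phase <- s$time - floor(s$time / 24) * 24
  lit <- phase <= L   # inclusive: points on the light-to-dark switch count
  if (sum(lit) < 2L)
    stop("need at least 2 observations in illuminated phases", call. = FALSE)
  x <- cumulative_light_h(s$time[lit], L)
  if (diff(range(x)) == 0)
    stop("illuminated observations span no illuminated time", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), s$feII[lit])
  structure(list(value = -unname(fit$coefficients[2]),
                 unit = "umol/l/h",
                 window = range(s$time[lit]), method = "regression",
                 corrected = isTRUE(attr(s, "corrected")),
                 negative = unname(fit$coefficients[2]) > 0),
            class = "rate_estimate")
}

#' Scale an hourly rate to a daily rate
#'
#' Product of the hourly rate and the number of hours per day over which
#' it applies. The choice of hours (e.g. 12 h of daily illumination vs a
#' 24 h day) is the caller's, made explicit, never implicit.
#'
#' @param hourly rate in umol l-1 h-1 (numeric or `rate_estimate`).
#' @param hours_per_day hours in (0, 24].
#' @return Daily rate in umol l-1 d-1 (numeric scalar).
#' @examples
#' daily_rate(2.65, 24)   # 63.6
#' @export
daily_rate <- function(hourly, hours_per_day) {
  v <- if (inherits(hourly, "rate_estimate")) hourly$value else hourly
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("hourly rate must be a finite scalar", call. = FALSE)
  if (!(hours_per_day > 0 && hours_per_day <= 24))
    stop("hours_per_day must be in (0, 24]", call. = FALSE)
  v * hours_per_day
}
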