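# Inorganic-carbon uptake from 14C-bicarbonate incubations, and
# stoichiometric conversion of Fe(II)-stimulated photosynthetic carbon
# uptake into a volumetric Fe(II)-oxidation rate.

# fixed isotope-fractionation correction between 12C and 14C
C14_FRACTIONATION <- 1.06

#' Construct a 14C-bicarbonate tracer incubation record
#'
#' Counts are blank-corrected upstream (filter counts minus killed
#' control), so `c14_fixed` may be zero but not negative.
#'
#' @param treatment treatment label, e.g. `"Fe(II)+DCMU"`.
#' @param light logical, incubated in the light?
#' @param c14_fixed blank-corrected radioactivity fixed on the filter
#'   (counts, e.g. DPM).
#' @param total_activity total DIC radioactivity per vial (same counts
#'   unit), positive.
#' @param dic dissolved inorganic carbon at the sampling depth, ug C l-1.
#' @param duration_h incubation time in h, positive.
#' @param dcmu logical, PSII inhibitor added?
#' @return A `tracer_incubation` list.
#' @export
tracer_incubation <- function(treatment, light, c14_fixed, total_activity,
                              dic, duration_h, dcmu = FALSE) {
  if (!(total_activity > 0)) stop("total_activity must be positive", call. = FALSE)
  if (!(duration_h > 0)) stop("duration must be positive", call. = FALSE)
  if (c14_fixed < 0) stop("c14_fixed must be non-negative", call. = FALSE)
  if (!(dic > 0)) stop("dic must be positive", call. = FALSE)
  structure(list(treatment = treatment, light = isTRUE(light),
                 dcmu = isTRUE(dcmu), c14_fixed = c14_fixed,
                 total_activity = total_activity, dic = dic,
                 duration_h = duration_h),
            class = "tracer_incubation")
}

#' Carbon-uptake rate from one tracer incubation
#'
#' Rate = 14C-fixed x [DIC] x 1.06 / (total 14C activity x t), the 1.06
#' being the isotopic-fractionation correction between 12C and 14C. The
#' formula is the standard radiocarbon primary-production calculation; the
#' grouping (fraction of added label fixed per hour, scaled to the ambient
#' DIC pool) is the only dimensionally consistent one.
#'
#' @param s a [tracer_incubation()].
#' @return An `uptake_rate`: list with `value` (ug C l-1 h-1), `treatment`,
#'   `light`, `dcmu` and `net = FALSE`.
#' @examples
#' s <- tracer_incubation("Fe(II)", TRUE, c14_fixed = 100,
#'                        total_activity = 10000, dic = 24000, duration_h = 4)
#' uptake_rate(s)$value   # 63.6
#' @export
uptake_rate <- function(s) {
  stopifnot(inherits(s, "tracer_incubation"))
  v <- s$c14_fixed * s$dic * C14_FRACTIONATION /
    (s$total_activity * s$duration_h)
  structure(list(value = v, treatment = s$treatment, light = s$light,
                 dcmu = s$dcmu, net = FALSE),
            class = "uptake_rate")
}

#' Net photosynthetic uptake (light minus dark)
#'
#' Dark chemoautotrophic fixation is subtracted from the light incubation
#' of the same treatment. Negative nets are possible (dark chemoautotrophy
#' can exceed the light value) and are flagged, not rejected.
#'
#' @param light,dark `uptake_rate`s of the same treatment, light and dark.
#' @return An `uptake_rate` with `net = TRUE` and a `negative` flag.
#' @export
net_photosynthetic_uptake <- function(light, dark) {
  stopifnot(inherits(light, "uptake_rate"), inherits(dark, "uptake_rate"))
  if (!identical(light$treatment, dark$treatment))
    stop("treatment mismatch: '", light$treatment, "' vs '",
         dark$treatment, "'", call. = FALSE)
  if (!light$light || dark$light)
    stop("expected a light and a dark rate, in that order", call. = FALSE)
  v <- light$value - dark$value
  structure(list(value = v, treatment = light$treatment, light = NA,
                 dcmu = light$dcmu, net = TRUE, negative = v < 0),
            class = "uptake_rate")
}

#' @export
print.uptake_rate <- function(x, ...) {
  cat("<uptake_rate> ", x$treatment, ": ", format(x$value, digits = 4),
      " ug C l-1 h-1",
      if (isTRUE(x$net)) " (net, light - dark)" else
        if (isTRUE(x$light)) " (light)" else " (dark)",
      if (isTRUE(x$negative)) " [negative]", "\n", sep = "")
  invisible(x)
}

#' Fe(II)-oxidation rate from Fe(II)-stimulated carbon uptake
#'
#' Converts the excess carbon fixation of an Fe(II)-amended treatment over
#' its control into an Fe(II)-oxidation rate via the electron-balance
#' stoichiometry of photoferrotrophy (4 Fe(II) oxidized per CO2
#' assimilated), integrated over the stated daily illumination period.
#'
#' @param treatment_rate,control_rate carbon-uptake rates in ug C l-1 h-1
#'   (numeric, or `uptake_rate` objects).
#' @param ratio mol Fe(II) oxidized per mol C fixed (from
#'   [donor_per_carbon_ratio()]); positive.
#' @param illuminated_hours_per_day daily illumination in h, in (0, 24].
#' @param molar_mass_c molar mass of carbon in g mol-1 (default 12.011).
#' @return A [volumetric_rate()] in umol Fe(II) l-1 d-1, method
#'   `"tracer"`, with attribute `nonpositive = TRUE` when the treatment did
#'   not exceed the control.
#' @examples
#' fe_oxidation_from_carbon(1.36, 0.72, ratio = 4,
#'                          illuminated_hours_per_day = 12)$value  # ~2.56
#' @export
fe_oxidation_from_carbon <- function(treatment_rate, control_rate, ratio,
                                     illuminated_hours_per_day,
                                     molar_mass_c = 12.011) {
  num <- function(x) if (inherits(x, "uptake_rate")) x$value else x
  tr <- num(treatment_rate); ctl <- num(control_rate)
  if (!(ratio > 0)) stop("ratio must be positive", call. = FALSE)
  if (!(illuminated_hours_per_day > 0 && illuminated_hours_per_day <= 24))
    stop("illuminated hours per day must be in (0, 24]", call. = FALSE)
  if (!(molar_mass_c > 0)) stop("molar mass must be positive", call. = FALSE)
  # ug C l-1 h-1 / (g mol-1) = umol C l-1 h-1
  v <- (tr - ctl) / molar_mass_c * ratio * illuminated_hours_per_day
  out <- volumetric_rate(v, unit = "umol/l/d", method = "tracer",
                         layer = "Fe(II)-stimulated net carbon fixation")
  attr(out, "nonpositive") <- v <= 0
  out
}

#' Descriptive summary of tracer incubations by treatment
#'
#' Mean and unbiased (n-1) standard deviation of the uptake rate per
#' treatment x light group, and the net (mean light minus mean dark)
#' uptake per treatment. No significance testing: descriptive only.
#'
#' @param samples list of [tracer_incubation()]s.
#' @return A list of two data frames: `groups` (treatment, dcmu, light, n,
#'   mean, sd; sd is `NA` for singleton groups) and `net` (treatment, dcmu,
#'   net = mean light - mean dark, where both phases exist).
#' @export
treatment_summary <- function(samples) {
  if (!length(samples)) stop("no samples", call. = FALSE)
  stopifnot(all(vapply(samples, inherits, TRUE, "tracer_incubation")))
  tab <- do.call(rbind, lapply(samples, function(s)
    data.frame(treatment = s$treatment, dcmu = s$dcmu, light = s$light,
               rate = uptake_rate(s)$value)))
  groups <- do.call(rbind, lapply(
    split(tab, interaction(tab$treatment, tab$dcmu, tab$light, drop = TRUE)),
    function(g) data.frame(
      treatment = g$treatment[1], dcmu = g$dcmu[1], light = g$light[1],
      n = nrow(g), mean = mean(g$rate),
      sd = if (nrow(g) > 1L) stats::sd(g$rate) else NA_real_)))
  rownames(groups) <- NULL
  net <- do.call(rbind, lapply(
    split(groups, interaction(groups$treatment, groups$dcmu, drop = TRUE)),
    function(g) {
      if (!any(g$light) || !any(!g$light)) return(NULL)
      data.frame(treatment = g$treatment[1], dcmu = g$dcmu[1],
                 net = g$mean[g$light] - g$mean[!g$light])
    }))
  if (!is.null(net)) rownames(net) <- NULL
  list(groups = groups, net = net)
}
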