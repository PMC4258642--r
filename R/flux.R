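# Fickian diffusive flux across the chemocline and derived volumetric
# Fe(II)-oxidation rates; areal deposition-flux scaling for comparison
# with Banded Iron Formation accumulation.

SECONDS_PER_DAY <- 86400
DAYS_PER_YEAR <- 365   # 365-day year; the BIF areal flux is defined on it

#' Diffusive flux from a linear gradient and an eddy diffusivity
#'
#' Fick's first law F_z = -K_z * (dC/dz) with depth positive downward, so a
#' concentration increasing with depth drives an upward flux. Magnitude is
#' reported per day.
#'
#' @param gradient a [linear_gradient()] or a numeric slope in umol cm-4.
#' @param k_z vertical eddy diffusivity in cm2 s-1, positive.
#' @return A `diffusive_flux`: list with `magnitude` (umol cm-2 d-1),
#'   `direction` (`"upward"`, `"downward"` or `"none"`), `k_z` and
#'   `gradient` (umol cm-4).
#' @examples
#' diffusive_flux(7.07e-4, k_z = 5e-4)   # 0.031 umol cm-2 d-1, upward
#' @export
diffusive_flux <- function(gradient, k_z) {
  slope <- if (inherits(gradient, "linear_gradient")) gradient$slope else gradient
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope))
    stop("gradient must be a finite scalar or linear_gradient", call. = FALSE)
  if (!is.numeric(k_z) || length(k_z) != 1L || !(k_z > 0))
    stop("k_z must be positive", call. = FALSE)
  structure(list(
    magnitude = k_z * abs(slope) * SECONDS_PER_DAY,
    direction = if (slope > 0) "upward" else if (slope < 0) "downward" else "none",
    k_z = k_z,
    gradient = slope),
    class = "diffusive_flux")
}

#' @export
print.diffusive_flux <- function(x, ...) {
  cat("<diffusive_flux> ", format(round(x$magnitude, 3), nsmall = 3),
      " umol cm-2 d-1 ", x$direction,
      " (K_z = ", format(x$k_z), " cm2 s-1, gradient = ",
      format(x$gradient, digits = 4), " umol cm-4)\n", sep = "")
  invisible(x)
}

#' Volumetric rate from a flux consumed within a water-column layer
#'
#' Spreads an areal flux over a layer of the stated thickness: the
#' volumetric turnover rate that would consume the arriving flux, per day.
#'
#' @param flux a [diffusive_flux()] or numeric magnitude in umol cm-2 d-1.
#' @param layer_thickness_m layer thickness in m, positive.
#' @return A `volumetric_rate` (see [volumetric_rate()]) in umol l-1 d-1,
#'   method `"flux"`.
#' @examples
#' layer_volumetric_rate(diffusive_flux(7.07e-4, 5e-4), 1.75)  # 0.174
#' @export
layer_volumetric_rate <- function(flux, layer_thickness_m) {
  mag <- if (inherits(flux, "diffusive_flux")) flux$magnitude else flux
  if (!is.numeric(mag) || length(mag) != 1L || !is.finite(mag) || mag < 0)
    stop("flux magnitude must be a non-negative scalar", call. = FALSE)
  if (!is.numeric(layer_thickness_m) || length(layer_thickness_m) != 1L ||
      !(layer_thickness_m > 0))
    stop("layer thickness must be positive", call. = FALSE)
  thickness_cm <- layer_thickness_m * 100
  volumetric_rate(mag / thickness_cm * 1000,  # cm3 -> l
                  unit = "umol/l/d", method = "flux",
                  layer = sprintf("%g m layer", layer_thickness_m))
}

#' Construct a volumetric rate record
#'
#' @param value rate value.
#' @param unit `"umol/l/d"` or `"umol/l/h"`.
#' @param method one of `"flux"`, `"tracer"`, `"incubation"`.
#' @param layer free-text description of the layer/window the rate refers to.
#' @return A `volumetric_rate` list.
#' @export
volumetric_rate <- function(value, unit = c("umol/l/d", "umol/l/h"),
                            method = c("flux", "tracer", "incubation"),
                            layer = "") {
  unit <- match.arg(unit)
  method <- match.arg(method)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("rate value must be a finite scalar", call. = FALSE)
  structure(list(value = value, unit = unit, method = method, layer = layer),
            class = "volumetric_rate")
}

#' @export
print.volumetric_rate <- function(x, ...) {
  cat("<volumetric_rate> ", format(round(x$value, 3), nsmall = 3), " ",
      x$unit, " [", x$method, if (nzchar(x$layer)) paste0("; ", x$layer),
      "]\n", sep = "")
  invisible(x)
}

#' Areal deposition flux from a basin-wide precipitation rate
#'
#' Scales a whole-basin iron precipitation rate (mol per 365-day year) to
#' an areal flux in umol cm-2 d-1, for comparing a modern chemocline iron
#' flux with what sustained deposition of a Banded Iron Formation would
#' have required.
#'
#' @param total_rate_mol_yr basin-wide rate in mol yr-1, non-negative.
#' @param area_m2 basin area in m2, positive.
#' @return Areal flux in umol cm-2 d-1 (numeric scalar).
#' @examples
#' areal_deposition_flux(4.5e12, 1e11)   # 12.3 umol cm-2 d-1
#' @export
areal_deposition_flux <- function(total_rate_mol_yr, area_m2) {
  if (!is.numeric(total_rate_mol_yr) || length(total_rate_mol_yr) != 1L ||
      !is.finite(total_rate_mol_yr) || total_rate_mol_yr < 0)
    stop("total rate must be non-negative", call. = FALSE)
  if (!is.numeric(area_m2) || length(area_m2) != 1L || !(area_m2 > 0))
    stop("area must be positive", call. = FALSE)
  mol_per_m2_day <- total_rate_mol_yr / area_m2 / DAYS_PER_YEAR
  mol_per_m2_day / 1e4 * 1e6   # m-2 -> cm-2, mol -> umol
}
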