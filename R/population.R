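# Photoferrotroph population size from a bulk Fe(II)-oxidation rate and a
# cell-specific rate, expressed as a fraction of a counted population.

#' Cell-specific Fe(II)-oxidation rate default
#'
#' A deliberately low literature value (pmol Fe(II) h-1 cell-1, from a
#' phototrophic Fe(II)-oxidizer pure culture) so that the inferred
#' population size is not underestimated. Overridable everywhere it is
#' used.
#' @export
DEFAULT_CELL_RATE_PMOL_H <- 32

#' Photoferrotroph cell density from a bulk oxidation rate
#'
#' Divides the bulk volumetric Fe(II)-oxidation rate by the per-cell rate:
#' density = bulk rate (converted to pmol ml-1 h-1, factor 1000 from
#' umol l-1 h-1) / cell rate.
#'
#' @param bulk_rate_umol_l_h bulk Fe(II)-oxidation rate in umol l-1 h-1,
#'   non-negative.
#' @param cell_rate_pmol_h cell-specific rate in pmol Fe(II) h-1 cell-1,
#'   positive (default [DEFAULT_CELL_RATE_PMOL_H]).
#' @return Cell density in cells ml-1 (numeric scalar).
#' @examples
#' photoferrotroph_density(2.65)   # ~82.8 cells ml-1
#' @export
photoferrotroph_density <- function(bulk_rate_umol_l_h,
                                    cell_rate_pmol_h = DEFAULT_CELL_RATE_PMOL_H) {
  if (!(cell_rate_pmol_h > 0))
    stop("cell-specific rate must be positive", call. = FALSE)
  if (!is.numeric(bulk_rate_umol_l_h) || bulk_rate_umol_l_h < 0)
    stop("bulk rate must be non-negative", call. = FALSE)
  bulk_rate_umol_l_h * 1000 / cell_rate_pmol_h
}

#' Fraction of a counted reference population
#'
#' @param density cells ml-1, non-negative.
#' @param reference counted reference population in cells ml-1, positive
#'   (e.g. the green-sulfur-bacteria count at the incubation depth).
#' @return Percentage (0-100+ scale).
#' @examples
#' fraction_of_population(82.8, 0.03e5)   # ~2.76 -> "about 3%"
#' @export
fraction_of_population <- function(density, reference) {
  if (!(reference > 0)) stop("reference count must be positive", call. = FALSE)
  if (density < 0) stop("density must be non-negative", call. = FALSE)
  100 * density / reference
}

#' Full population estimate record
#'
#' Composes [photoferrotroph_density()] and [fraction_of_population()].
#'
#' @inheritParams photoferrotroph_density
#' @param reference_cells_ml counted reference population, cells ml-1, or
#'   `NA` to skip the fraction.
#' @return A `population_estimate` list: `density`, `cell_specific_rate`,
#'   `reference_count`, `fraction_of_reference` (percent, `NA` without a
#'   reference).
#' @export
population_estimate <- function(bulk_rate_umol_l_h,
                                cell_rate_pmol_h = DEFAULT_CELL_RATE_PMOL_H,
                                reference_cells_ml = NA_real_) {
  d <- photoferrotroph_density(bulk_rate_umol_l_h, cell_rate_pmol_h)
  frac <- if (is.finite(reference_cells_ml))
    fraction_of_population(d, reference_cells_ml) else NA_real_
  structure(list(density = d, cell_specific_rate = cell_rate_pmol_h,
                 reference_count = reference_cells_ml,
                 fraction_of_reference = frac),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat("<population_estimate> ", format(x$density, digits = 4),
      " cells ml-1 (cell rate ", x$cell_specific_rate,
      " pmol Fe(II) h-1 cell-1)", sep = "")
  if (is.finite(x$fraction_of_reference))
    cat(" = about ", round(x$fraction_of_reference), "% of ",
        format(x$reference_count, scientific = TRUE, digits = 2),
        " cells ml-1", sep = "")
  cat("\n")
  invisible(x)
}
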