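# Unit-aware depth profiles and linear gradient estimation.
#
# Canonical internal units match the flux-calculation convention:
# depth cm (positive downward), concentration umol cm^-3, time days.
# All I/O converts at the boundary.

# recognized concentration units, as multiplicative factor to uM
CONC_UNIT_TO_UM <- c(
  "uM"          = 1,
  "mM"          = 1000,
  "umol/l"      = 1,
  "umol/cm3"    = 1000,
  "mol/m3"      = 1000)

normalize_conc_unit <- function(unit) {
  u <- trimws(unit)
  u <- gsub("μ", "u", u)           # micro sign variants
  u <- gsub("µ", "u", u)
  u <- gsub("\\s+", "", u)
  u <- sub("\\^(-?[0-9]+)", "\\1", u)   # cm^3 -> cm3
  key <- c(
    "uM" = "uM",
    "mM" = "mM",
    "umol/l" = "umol/l", "umol/L" = "umol/l", "umoll-1" = "umol/l",
    "umol/cm3" = "umol/cm3", "umolcm-3" = "umol/cm3",
    "mol/m3" = "mol/m3", "molm-3" = "mol/m3")
  if (!(u %in% names(key)))
    stop("unknown concentration unit: '", unit, "'", call. = FALSE)
  key[[u]]
}

#' Convert between concentration units
#'
#' Exact factor conversion among uM, mM, umol l-1, umol cm-3 and mol m-3
#' (1 uM = 1e-3 umol cm-3 = 1e-3 mol m-3).
#'
#' @param value numeric concentration value(s).
#' @param from_unit,to_unit unit names (micro sign or `u` spelling both
#'   accepted, e.g. `"uM"`, `"umol/cm3"`, `"mol/m3"`).
#' @return Converted numeric value(s).
#' @examples
#' convert_concentration(230, "uM", "umol/cm3")  # 0.230
#' @export
convert_concentration <- function(value, from_unit, to_unit) {
  f <- CONC_UNIT_TO_UM[[normalize_conc_unit(from_unit)]]
  t <- CONC_UNIT_TO_UM[[normalize_conc_unit(to_unit)]]
  value * f / t
}

#' Construct a depth profile
#'
#' @param analyte analyte name, e.g. `"FeII"`.
#' @param depth_m numeric depths in m below surface, strictly increasing.
#' @param value numeric concentrations, same length as `depth_m`.
#' @param unit concentration unit of `value`.
#' @return A `depth_profile`: data frame with columns `depth_m` and `value`
#'   plus attributes `analyte` and `unit`.
#' @export
depth_profile <- function(analyte, depth_m, value, unit) {
  if (length(depth_m) != length(value))
    stop("depth and value lengths differ", call. = FALSE)
  if (length(depth_m) == 0L)
    stop("profile has no samples", call. = FALSE)
  if (anyNA(depth_m) || anyNA(value) || !all(is.finite(depth_m)) || !all(is.finite(value)))
    stop("profile depths and values must be finite", call. = FALSE)
  o <- order(depth_m)
  depth_m <- depth_m[o]; value <- value[o]
  if (any(diff(depth_m) <= 0))
    stop("depths must be strictly increasing (duplicate depth?)", call. = FALSE)
  unit <- normalize_conc_unit(unit)
  structure(data.frame(depth_m = depth_m, value = value),
            analyte = analyte, unit = unit,
            class = c("depth_profile", "data.frame"))
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("<depth_profile> ", attr(x, "analyte"), " [", attr(x, "unit"), "], ",
      nrow(x), " samples, ", min(x$depth_m), "-", max(x$depth_m), " m\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read one analyte's depth profile from a delimited table
#'
#' Expects a header with columns `depth_m`, `analyte`, `value`, `unit`
#' (comma- or tab-separated, inferred from the header line). Rows for the
#' requested analyte are extracted and sorted by depth.
#'
#' @param path file path or a connection.
#' @param analyte analyte name to extract.
#' @return A [depth_profile()].
#' @export
read_profile <- function(path, analyte) {
  first <- if (inherits(path, "connection")) {
    stop("pass a file path", call. = FALSE)
  } else readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("depth_m", "analyte", "value", "unit")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("profile table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab <- tab[tab$analyte == analyte, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no rows for analyte '", analyte, "'", call. = FALSE)
  units <- unique(vapply(tab$unit, normalize_conc_unit, ""))
  if (length(units) != 1L)
    stop("mixed units for analyte '", analyte, "': ",
         paste(units, collapse = ", "), call. = FALSE)
  depth_profile(analyte, tab$depth_m, tab$value, units)
}

#' Write depth profiles to a delimited file
#'
#' Emits the same `depth_m,analyte,value,unit` dialect that
#' [read_profile()] consumes; several profiles may be stacked in one file.
#'
#' @param profiles a `depth_profile` or list of them.
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, sep = ",") {
  if (inherits(profiles, "depth_profile")) profiles <- list(profiles)
  tabs <- lapply(profiles, function(p)
    data.frame(depth_m = p$depth_m, analyte = attr(p, "analyte"),
               value = p$value, unit = attr(p, "unit")))
  utils::write.table(do.call(rbind, tabs), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linear concentration gradient over a depth window
#'
#' Ordinary least-squares slope of concentration versus depth over the
#' samples falling inside `[z_top, z_bottom]` (inclusive), reported in the
#' canonical flux units umol cm-4. With exactly two in-window samples this
#' reduces to rise over run.
#'
#' @param p a [depth_profile()].
#' @param z_top,z_bottom window bounds in m, `z_top < z_bottom`.
#' @return A `linear_gradient`: list with `analyte`, `window` (m),
#'   `slope` (umol cm-4), `intercept` (umol cm-3 at depth 0) and `n` (number
#'   of samples used).
#' @examples
#' p <- depth_profile("FeII", c(15, 18), c(0, 212.1), "uM")
#' linear_gradient(p, 15, 18)$slope   # 7.07e-4 umol cm-4
#' @export
linear_gradient <- function(p, z_top, z_bottom) {
  stopifnot(inherits(p, "depth_profile"))
  if (!(z_top < z_bottom)) stop("z_top must be < z_bottom", call. = FALSE)
  sel <- p$depth_m >= z_top & p$depth_m <= z_bottom
  if (sum(sel) < 2L)
    stop("need at least 2 samples in [", z_top, ", ", z_bottom, "] m; got ",
         sum(sel), call. = FALSE)
  depth_cm <- p$depth_m[sel] * 100
  conc <- convert_concentration(p$value[sel], attr(p, "unit"), "umol/cm3")
  fit <- stats::lm.fit(cbind(1, depth_cm), conc)
  structure(list(analyte = attr(p, "analyte"),
                 window = c(z_top = z_top, z_bottom = z_bottom),
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n = sum(sel)),
            class = "linear_gradient")
}

#' @export
print.linear_gradient <- function(x, ...) {
  cat("<linear_gradient> ", x$analyte, " over ", x$window[1], "-",
      x$window[2], " m: ", format(x$slope, digits = 4),
      " umol cm-4 (n = ", x$n, ")\n", sep = "")
  invisible(x)
}
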