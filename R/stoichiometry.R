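# Stoichiometric algebra for the redox reactions of photoferrotrophic
# primary production and anaerobic organic-matter degradation.
#
# Sign convention: reactants carry negative coefficients, products positive.
# Coefficients are exact rationals; balance checks are exact.

# IUPAC element symbols (1-118); used to validate parsed formulas.
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Parse a chemical species from formula text
#'
#' Reads a formula of element symbols with optional integer subscripts and
#' an optional trailing charge. Both caret (`"Fe^2+"`, `"SO4^2-"`) and bare
#' (`"Fe2+"`, `"SO42-"`) charge dialects are accepted; a lone trailing sign
#' means charge one (`"H+"`).
#'
#' @param text formula text, e.g. `"FeOOH"`, `"SO4^2-"`, `"H+"`.
#' @return A `chem_species` with fields `label` (canonical normal form),
#'   `composition` (named integer vector, element -> atom count) and
#'   `charge` (signed integer).
#' @examples
#' parse_species("SO4^2-")
#' parse_species("CH2O")
#' @export
parse_species <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("species text must be a non-empty string", call. = FALSE)
  s <- trimws(text)

  charge <- 0L
  # caret dialect: trailing ^<digits><sign> or ^<sign>
  m <- regmatches(s, regexec("\\^([0-9]*)([+-])$", s))[[1]]
  if (length(m)) {
    n <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    charge <- if (m[3] == "+") n else -n
    s <- sub("\\^[0-9]*[+-]$", "", s)
  } else {
    # bare dialect: trailing <digit><sign> or lone <sign>; only a single
    # charge digit, so "SO42-" reads as SO4 with charge 2- (a multi-digit
    # charge needs the caret dialect)
    m <- regmatches(s, regexec("([0-9]?)([+-])$", s))[[1]]
    if (length(m)) {
      n <- if (nzchar(m[2])) as.integer(m[2]) else 1L
      charge <- if (m[3] == "+") n else -n
      s <- sub("[0-9]?[+-]$", "", s)
    }
  }

  if (!nzchar(s)) stop("no element part in species: ", text, call. = FALSE)
  if (grepl("[+^-]", s))
    stop("malformed charge suffix in species: ", text, call. = FALSE)

  comp <- integer(0)
  rest <- s
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (!length(m) || !nzchar(m[1]))
      stop("cannot parse formula near '", rest, "' in species: ", text, call. = FALSE)
    sym <- m[2]
    if (!(sym %in% ELEMENT_SYMBOLS))
      stop("unknown element symbol '", sym, "' in species: ", text, call. = FALSE)
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (n <= 0L) stop("non-positive subscript in species: ", text, call. = FALSE)
    comp[sym] <- (if (sym %in% names(comp)) comp[[sym]] else 0L) + n
    rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
  }

  structure(
    list(label = species_label(comp, charge), composition = comp, charge = charge),
    class = "chem_species")
}

# canonical label: formula in first-appearance order with caret charge
species_label <- function(composition, charge) {
  body <- paste0(names(composition),
                 ifelse(composition > 1L, composition, ""), collapse = "")
  if (charge == 0L) return(body)
  mag <- if (abs(charge) > 1L) abs(charge) else ""
  paste0(body, "^", mag, if (charge > 0L) "+" else "-")
}

#' @export
print.chem_species <- function(x, ...) {
  cat("<chem_species> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Construct a reaction from species and signed rational coefficients
#'
#' @param id reaction identifier.
#' @param species list of `chem_species` (or formula strings, parsed on the
#'   fly).
#' @param coefficients list/vector of signed coefficients (reactants
#'   negative, products positive); integers or `rational`s or `"p/q"`
#'   strings.
#' @return A `reaction`: list with `id`, `species` (named list keyed by
#'   canonical label) and `coef` (named list of `rational`). No zero
#'   coefficients are stored.
#' @export
reaction <- function(id, species, coefficients) {
  if (length(species) != length(coefficients))
    stop("species and coefficients differ in length", call. = FALSE)
  sp <- lapply(species, function(s)
    if (inherits(s, "chem_species")) s else parse_species(s))
  cf <- lapply(coefficients, as_rational)
  labels <- vapply(sp, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate species in reaction: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  keep <- !vapply(cf, rat_is_zero, TRUE)
  sp <- sp[keep]; cf <- cf[keep]; labels <- labels[keep]
  names(sp) <- labels; names(cf) <- labels
  signs <- vapply(cf, function(r) sign(r$num), 0)
  if (!any(signs < 0) || !any(signs > 0))
    stop("reaction needs at least one reactant and one product", call. = FALSE)
  structure(list(id = id, species = sp, coef = cf), class = "reaction")
}

#' Parse a reaction from arrow notation
#'
#' Reads one reaction in `"2 CO2 + 8 Fe^2+ + 14 H2O -> 2 CH2O + 8 FeOOH +
#' 16 H+"` syntax. Coefficients may be integers or `p/q` fractions; a
#' missing coefficient means 1.
#'
#' @param text the reaction line.
#' @param id reaction identifier (defaults to the text itself).
#' @return A `reaction`.
#' @export
parse_reaction <- function(text, id = trimws(text)) {
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("reaction must contain exactly one '->': ", text, call. = FALSE)
  parse_side <- function(side, sgn) {
    # term separators are '+' flanked by whitespace; a charge '+' is always
    # attached to its species token ("Fe^2+", "H+"), never space-separated
    terms <- strsplit(trimws(side), "\\s+\\+(\\s+|$)")[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (!length(terms)) stop("empty reaction side: ", side, call. = FALSE)
    lapply(terms, function(term) {
      m <- regmatches(term, regexec("^([0-9]+(?:/[0-9]+)?)\\s+(.*)$", term))[[1]]
      if (length(m)) {
        list(coef = rat_scale_int(as_rational(m[2]), sgn), sp = parse_species(m[3]))
      } else {
        list(coef = rational(sgn), sp = parse_species(term))
      }
    })
  }
  terms <- c(parse_side(sides[1], -1L), parse_side(sides[2], +1L))
  reaction(id,
           species = lapply(terms, `[[`, "sp"),
           coefficients = lapply(terms, `[[`, "coef"))
}

#' @export
print.reaction <- function(x, ...) {
  cat("<reaction> ", x$id, ": ", format_reaction(x), "\n", sep = "")
  invisible(x)
}

#' Render a reaction in arrow form
#'
#' @param r a `reaction`.
#' @return A single string, reactants and products restored to arrow form.
#' @export
format_reaction <- function(r) {
  side <- function(sel) {
    labs <- names(r$coef)[sel]
    parts <- vapply(labs, function(l) {
      c0 <- r$coef[[l]]
      mag <- rational(abs(c0$num), c0$den)
      if (mag$num == mag$den) l else paste(format(mag), l)
    }, "")
    paste(parts, collapse = " + ")
  }
  signs <- vapply(r$coef, function(c0) sign(c0$num), 0)
  paste(side(signs < 0), "->", side(signs > 0))
}

#' Check atom and charge balance of a reaction
#'
#' Sums, per element, coefficient times atom count over all species, and
#' likewise for charge. All arithmetic is exact rational, so `balanced` is
#' true iff every net is identically zero.
#'
#' @param r a `reaction`.
#' @return A `balance_report`: list with `element_net` (named list of
#'   `rational`, every element appearing in the reaction), `charge_net`
#'   (`rational`) and `balanced` (logical).
#' @examples
#' r <- parse_reaction("2 CO2 + 8 Fe^2+ + 14 H2O -> 2 CH2O + 8 FeOOH + 16 H+")
#' balance_report(r)$balanced
#' @export
balance_report <- function(r) {
  stopifnot(inherits(r, "reaction"))
  elements <- unique(unlist(lapply(r$species, function(s) names(s$composition))))
  net <- lapply(elements, function(e) {
    tot <- rational(0)
    for (lab in names(r$coef)) {
      cnt <- r$species[[lab]]$composition
      if (e %in% names(cnt))
        tot <- rat_add(tot, rat_scale_int(r$coef[[lab]], cnt[[e]]))
    }
    tot
  })
  names(net) <- elements
  qnet <- rational(0)
  for (lab in names(r$coef))
    qnet <- rat_add(qnet, rat_scale_int(r$coef[[lab]], r$species[[lab]]$charge))
  balanced <- all(vapply(net, rat_is_zero, TRUE)) && rat_is_zero(qnet)
  structure(list(element_net = net, charge_net = qnet, balanced = balanced),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> ", if (x$balanced) "balanced" else "NOT balanced", "\n")
  for (e in names(x$element_net))
    cat("  ", e, ": ", format(x$element_net[[e]]), "\n", sep = "")
  cat("  charge: ", format(x$charge_net), "\n", sep = "")
  invisible(x)
}

#' Linearly combine two balanced reactions
#'
#' Coefficients are summed termwise after scaling; species whose net
#' coefficient cancels to zero are dropped. The result is reduced so the
#' greatest common divisor of all coefficient numerators and denominators
#' is 1, matching how combined stoichiometries are conventionally printed.
#'
#' @param a,b `reaction`s, both balanced.
#' @param scale_a,scale_b rational scale factors (default 1).
#' @param id identifier for the combined reaction.
#' @return The combined `reaction`.
#' @examples
#' eqs <- redox_reactions()
#' combine_reactions(eqs$photoferrotrophy, eqs$sulfate_respiration)
#' @export
combine_reactions <- function(a, b, scale_a = 1, scale_b = 1,
                              id = paste(a$id, "+", b$id)) {
  stopifnot(inherits(a, "reaction"), inherits(b, "reaction"))
  if (!balance_report(a)$balanced) stop("reaction ", a$id, " is not balanced", call. = FALSE)
  if (!balance_report(b)$balanced) stop("reaction ", b$id, " is not balanced", call. = FALSE)
  sa <- as_rational(scale_a); sb <- as_rational(scale_b)

  sp <- c(a$species, b$species)
  sp <- sp[!duplicated(names(sp))]
  labels <- names(sp)
  cf <- lapply(labels, function(l) {
    tot <- rational(0)
    if (l %in% names(a$coef)) tot <- rat_add(tot, rat_mul(a$coef[[l]], sa))
    if (l %in% names(b$coef)) tot <- rat_add(tot, rat_mul(b$coef[[l]], sb))
    tot
  })
  names(cf) <- labels
  keep <- !vapply(cf, rat_is_zero, TRUE)
  if (!any(keep))
    stop("complete cancellation: combined reaction has no terms", call. = FALSE)
  cf <- cf[keep]; sp <- sp[keep]
  signs <- vapply(cf, function(r) sign(r$num), 0)
  if (!any(signs < 0) || !any(signs > 0))
    stop("complete cancellation: combined reaction has no ",
         if (any(signs > 0)) "reactants" else "products", call. = FALSE)

  # normalize to lowest integer terms: clear denominators, divide by gcd
  l <- 1
  for (r0 in cf) l <- lcm2(l, r0$den)
  cf <- lapply(cf, function(r0) rat_scale_int(r0, l))
  g <- 0
  for (r0 in cf) g <- gcd2(g, abs(r0$num))
  cf <- lapply(cf, function(r0) rational(r0$num / g, 1))
  reaction(id, species = sp, coefficients = cf)
}

#' Electron-donor-per-carbon stoichiometric ratio
#'
#' Ratio of the absolute reactant coefficients of the electron donor and
#' the carbon source, e.g. 4 Fe(II) oxidized per CO2 assimilated for
#' photoferrotrophic primary production. Invariant under uniform scaling of
#' the reaction.
#'
#' @param r a `reaction`.
#' @param donor,carbon_source species labels or `chem_species` that appear
#'   as reactants in `r`.
#' @return The ratio as a numeric scalar.
#' @examples
#' donor_per_carbon_ratio(redox_reactions()$photoferrotrophy, "Fe^2+", "CO2")
#' @export
donor_per_carbon_ratio <- function(r, donor, carbon_source) {
  stopifnot(inherits(r, "reaction"))
  lab <- function(x) {
    if (inherits(x, "chem_species")) x$label else parse_species(x)$label
  }
  dl <- lab(donor); cl <- lab(carbon_source)
  for (l in c(dl, cl)) {
    if (!(l %in% names(r$coef)))
      stop("species ", l, " absent from reaction ", r$id, call. = FALSE)
    if (r$coef[[l]]$num >= 0)
      stop("species ", l, " is not a reactant in ", r$id, call. = FALSE)
  }
  d <- r$coef[[dl]]; cs <- r$coef[[cl]]
  abs(d$num / d$den) / abs(cs$num / cs$den)
}

#' Read a reaction registry from a plain-text file
#'
#' One reaction per line, `id: <arrow form>`; blank lines and `#` comments
#' ignored. The registry of photoferrotrophy and anaerobic-degradation
#' stoichiometries ships with the package (see [redox_reactions()]).
#'
#' @param path file path.
#' @return Named list of `reaction`s keyed by id.
#' @export
read_reactions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (!length(m)) stop("malformed reaction line: ", ln, call. = FALSE)
    id <- trimws(m[2])
    if (id %in% names(out)) stop("duplicate reaction id: ", id, call. = FALSE)
    out[[id]] <- parse_reaction(m[3], id = id)
  }
  out
}

#' The packaged redox-reaction registry
#'
#' The six stoichiometries of the study system: photoferrotrophic primary
#' production (`photoferrotrophy`), Fe(III) respiration, sulfate
#' respiration, methanogenesis, and the net combinations of primary
#' production with sulfate respiration and with methanogenesis.
#'
#' @return Named list of `reaction`s.
#' @export
redox_reactions <- function() {
  path <- system.file("extdata", "redox_reactions.txt", package = "ironcline",
                      mustWork = TRUE)
  read_reactions(path)
}
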