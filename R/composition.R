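#' Elemental composition of a chemical species
#'
#' Constructs the C/H/O/N + charge bookkeeping unit used throughout the
#' balancing machinery. Atom counts may be fractional, as is conventional for
#' C-mol biomass formulas such as \eqn{CH_{1.8}O_{0.5}N_{0.2}}.
#'
#' @param n_C,n_H,n_O,n_N Atoms per formula unit (non-negative reals).
#' @param charge Elementary charge per formula unit (real, signed).
#' @return An object of class `elemental_composition`.
#' @examples
#' elemental_composition(n_C = 2, n_H = 3, n_O = 2, charge = -1)  # acetate
#' elemental_composition(n_C = 1, n_H = 1.8, n_O = 0.5, n_N = 0.2) # biomass
#' @export
elemental_composition <- function(n_C = 0, n_H = 0, n_O = 0, n_N = 0, charge = 0) {
  atoms <- c(C = n_C, H = n_H, O = n_O, N = n_N)
  if (!all(is.finite(atoms)) || !is.finite(charge))
    stop("composition error: atom counts and charge must be finite", call. = FALSE)
  if (any(atoms < 0))
    stop("composition error: atom counts must be non-negative", call. = FALSE)
  if (all(atoms == 0) && charge == 0)
    stop("composition error: empty composition (all-zero atoms, zero charge)",
         call. = FALSE)
  structure(list(n_C = unname(n_C), n_H = unname(n_H), n_O = unname(n_O),
                 n_N = unname(n_N), charge = unname(charge)),
            class = "elemental_composition")
}

#' Parse a molecular formula string
#'
#' Accepts C/H/O/N formulas with optionally fractional subscripts
#' (`"CH1.8O0.5N0.2"`) and a trailing charge token (`"-"`, `"+"`, `"-2"`,
#' `"+2"` — sign first, so the last subscript is never mistaken for a charge
#' magnitude).
#'
#' @param formula A single formula string, e.g. `"C2H3O2-"` or `"N2O"`.
#' @return An `elemental_composition`.
#' @examples
#' parse_formula("C2H3O2-")        # acetate
#' parse_formula("NH4+")
#' parse_formula("CH1.8O0.5N0.2")  # standard biomass
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("\\s", "", formula)
  charge <- 0
  # charge token is a trailing sign optionally followed by its magnitude
  # ("-", "+", "-2", "+2"); a digit before the sign stays with the formula,
  # so "C2H3O2-" is O2 with charge -1, not O with charge -2
  m <- regmatches(s, regexec("([+-])([0-9]*)$", s))[[1]]
  if (length(m)) {
    mag <- if (nzchar(m[3])) as.numeric(m[3]) else 1
    charge <- if (m[2] == "+") mag else -mag
    s <- substr(s, 1L, nchar(s) - nchar(m[1]))
  }
  atoms <- c(C = 0, H = 0, O = 0, N = 0)
  pat <- "([A-Z][a-z]?)([0-9]*\\.?[0-9]*)"
  pos <- gregexpr(pat, s)[[1]]
  toks <- regmatches(s, gregexpr(pat, s))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != s)
    stop("cannot parse formula: ", formula, call. = FALSE)
  for (tok in toks) {
    p <- regmatches(tok, regexec(pat, tok))[[1]]
    el <- p[2]
    if (!el %in% names(atoms))
      stop("unsupported element '", el, "' in formula ", formula,
           " (only C, H, O, N are balanced)", call. = FALSE)
    n <- if (nzchar(p[3])) as.numeric(p[3]) else 1
    atoms[el] <- atoms[el] + n
  }
  elemental_composition(atoms["C"], atoms["H"], atoms["O"], atoms["N"], charge)
}

#' Degree of reduction of a composition
#'
#' Available electrons per formula unit relative to the reference redox states
#' H2O, CO2 and H+, with the nitrogen reference valence as a parameter:
#' \deqn{\gamma = 4 n_C + n_H - 2 n_O + v_N n_N - z.}
#' The classical convention for organic substrates and biomass takes the
#' ammonia reference (\eqn{v_N = -3}); for N-oxide electron acceptors the
#' dinitrogen reference (\eqn{v_N = 0}) gives the electrons accepted per mole
#' (e.g. \eqn{\gamma_{N_2O} = -2}, matching
#' \eqn{N_2O + 2H^+ + 2e^- \rightarrow N_2 + H_2O}).
#'
#' @param comp An `elemental_composition` (or formula string).
#' @param n_reference_valence Nitrogen reference valence \eqn{v_N};
#'   default `-3`.
#' @return Electrons per formula unit (scalar).
#' @examples
#' degree_of_reduction(parse_formula("C2H3O2-"))             # 8
#' degree_of_reduction(parse_formula("CH1.8O0.5N0.2"))        # 4.2
#' degree_of_reduction(parse_formula("N2O"), n_reference_valence = 0) # -2
#' @export
degree_of_reduction <- function(comp, n_reference_valence = -3) {
  if (is.character(comp)) comp <- parse_formula(comp)
  if (!inherits(comp, "elemental_composition"))
    stop("composition error: expected an elemental_composition", call. = FALSE)
  4 * comp$n_C + comp$n_H - 2 * comp$n_O +
    n_reference_valence * comp$n_N - comp$charge
}

#' Define a chemical species of a conversion system
#'
#' @param name Unique species identifier.
#' @param formula Formula string (see [parse_formula()]) or an
#'   `elemental_composition`.
#' @param measured Logical: was the conversion rate of this species measured?
#' @param role One of `"electron_donor"`, `"electron_acceptor"`, `"n_source"`,
#'   `"biomass"`, `"product"`.
#' @param phase Optional phase label (`"liquid"`, `"gas"`, `"solid"`).
#' @return An object of class `species`.
#' @export
species <- function(name, formula, measured = FALSE, role = "product",
                    phase = "liquid") {
  role <- match.arg(role,
                    c("electron_donor", "electron_acceptor", "n_source",
                      "biomass", "product"))
  comp <- if (is.character(formula)) parse_formula(formula) else formula
  if (!inherits(comp, "elemental_composition"))
    stop("composition error: invalid formula for species ", name, call. = FALSE)
  structure(list(name = name, composition = comp, measured = isTRUE(measured),
                 role = role, phase = phase),
            class = "species")
}

#' @export
print.species <- function(x, ...) {
  cat(sprintf("<species> %s  [%s%s]  C%g H%g O%g N%g charge %+g\n",
              x$name, x$role, if (x$measured) ", measured" else "",
              x$composition$n_C, x$composition$n_H, x$composition$n_O,
              x$composition$n_N, x$composition$charge))
  invisible(x)
}

#' Assemble a species system
#'
#' Validates a list of [species()] objects: names must be unique and at least
#' one species must be measured.
#'
#' @param ... `species` objects (or a single list of them).
#' @return A named list of species with class `species_system`.
#' @export
species_system <- function(...) {
  sp <- list(...)
  if (length(sp) == 1L && is.list(sp[[1]]) && !inherits(sp[[1]], "species"))
    sp <- sp[[1]]
  if (!all(vapply(sp, inherits, logical(1), "species")))
    stop("species_system expects species objects", call. = FALSE)
  nm <- vapply(sp, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate species names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  if (!any(vapply(sp, `[[`, logical(1), "measured")))
    stop("a species system needs at least one measured species", call. = FALSE)
  names(sp) <- nm
  structure(sp, class = "species_system")
}

#' The acetate / nitrous oxide enrichment system
#'
#' The default eight-species system of an N2O-respiring acetate-fed chemostat:
#' measured acetate, N2O, ammonium and biomass plus unmeasured CO2, N2, water
#' and protons. Biomass defaults to the standard composition
#' \eqn{CH_{1.8}O_{0.5}N_{0.2}} per C-mol, overridable.
#'
#' @param biomass_formula Biomass formula string per C-mol.
#' @return A `species_system`.
#' @examples
#' sys <- n2o_species_system()
#' names(sys)
#' @export
n2o_species_system <- function(biomass_formula = "CH1.8O0.5N0.2") {
  species_system(
    species("acetate", "C2H3O2-", measured = TRUE, role = "electron_donor"),
    species("n2o",     "N2O",     measured = TRUE, role = "electron_acceptor",
            phase = "gas"),
    species("nh4",     "NH4+",    measured = TRUE, role = "n_source"),
    species("biomass", biomass_formula, measured = TRUE, role = "biomass",
            phase = "solid"),
    species("co2",     "CO2", phase = "gas"),
    species("n2",      "N2",  phase = "gas"),
    species("h2o",     "H2O"),
    species("h",       "H+")
  )
}

#' Load species definitions from a YAML config file
#'
#' The file holds a `species:` list of entries with fields `name`, `formula`,
#' `measured`, `role` and optional `phase`.
#'
#' @param path Path to the YAML file.
#' @return A `species_system`.
#' @export
read_species_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species))
    stop("configuration error: no 'species' entry in ", path, call. = FALSE)
  sp <- lapply(cfg$species, function(e) {
    for (f in c("name", "formula"))
      if (is.null(e[[f]]))
        stop("configuration error: species entry missing '", f, "'",
             call. = FALSE)
    species(e$name, e$formula,
            measured = isTRUE(e$measured),
            role = if (is.null(e$role)) "product" else e$role,
            phase = if (is.null(e$phase)) "liquid" else e$phase)
  })
  species_system(sp)
}
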