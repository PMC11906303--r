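#' Conservation matrix of a species system
#'
#' One row per requested conserved quantity (C, H, O, N atoms and elementary
#' charge), one column per species, entries being the atom count (or charge)
#' of that quantity in that species.
#'
#' @param system A `species_system` (ordered list of [species()]).
#' @param balances Character subset of `c("C","H","O","N","charge")`, in the
#'   desired row order.
#' @return Numeric matrix with rownames = balances, colnames = species names.
#' @examples
#' conservation_matrix(n2o_species_system(), balances = c("C", "N"))
#' @export
conservation_matrix <- function(system,
                                balances = c("C", "H", "O", "N", "charge")) {
  if (length(balances) < 1L)
    stop("configuration error: empty balance set", call. = FALSE)
  bad <- setdiff(balances, c("C", "H", "O", "N", "charge"))
  if (length(bad))
    stop("configuration error: unknown balance(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!inherits(system, "species_system")) system <- species_system(system)
  if (length(system) < 2L)
    stop("configuration error: need at least two species", call. = FALSE)
  field <- c(C = "n_C", H = "n_H", O = "n_O", N = "n_N", charge = "charge")
  E <- vapply(system, function(sp)
    vapply(balances, function(b) sp$composition[[field[[b]]]], numeric(1)),
    numeric(length(balances)))
  E <- matrix(E, nrow = length(balances),
              dimnames = list(balances, names(system)))
  E
}

#' Balance a catabolic reaction exactly
#'
#' Solves the elemental and charge balances for the catabolic conversion of
#' one mole of electron donor by an electron acceptor into the stated
#' products; the donor coefficient is fixed at -1 and the unique coefficient
#' vector satisfying every requested conservation row is returned (products
#' positive, substrates negative). For acetate respired with N2O this yields
#' \deqn{CH_3COO^- + 4\,N_2O + H^+ \rightarrow 2\,CO_2 + 4\,N_2 + 2\,H_2O,}
#' i.e. 4 moles of N2O per mole of acetate.
#'
#' @param donor,acceptor [species()] objects (or formula strings).
#' @param products List of product species (or formula strings); character
#'   vectors are accepted. Additional substrates such as `"H+"` may appear
#'   here — their coefficients simply come out negative.
#' @param balances Conservation rows to enforce; default all five.
#' @param tol Absolute closure tolerance on each balance (default `1e-9`;
#'   coefficients of such systems are small-denominator rationals, so exact
#'   solves close far tighter than this).
#' @return A named numeric vector of stoichiometric coefficients with class
#'   `reaction_stoichiometry`.
#' @examples
#' rxn <- balance_catabolism(species("acetate", "C2H3O2-", role = "electron_donor"),
#'                           species("n2o", "N2O", role = "electron_acceptor"),
#'                           products = c("CO2", "N2", "H2O", "H+"))
#' rxn[["n2o"]]  # -4
#' @export
balance_catabolism <- function(donor, acceptor, products,
                               balances = c("C", "H", "O", "N", "charge"),
                               tol = 1e-9) {
  as_sp <- function(x, role) {
    if (inherits(x, "species")) x else species(x, x, role = role)
  }
  donor <- as_sp(donor, "electron_donor")
  acceptor <- as_sp(acceptor, "electron_acceptor")
  if (is.character(products)) products <- as.list(products)
  products <- lapply(products, as_sp, role = "product")
  sp <- c(list(donor, acceptor), products)
  names(sp) <- vapply(sp, `[[`, character(1), "name")
  # the measured flag is irrelevant here; mark the donor so the system validates
  sp[[1]]$measured <- TRUE
  system <- species_system(sp)
  E <- conservation_matrix(system, balances)
  A <- E[, -1L, drop = FALSE]          # unknown coefficients
  b <- E[, 1L]                         # donor column, coefficient -1
  qrA <- qr(A)
  if (qrA$rank < ncol(A))
    stop("stoichiometry error: reaction under-determined (",
         ncol(A) - qrA$rank, " free direction(s) among ",
         paste(colnames(A), collapse = ", "), ")", call. = FALSE)
  x <- qr.coef(qrA, b)
  resid <- as.vector(A %*% x - b)
  if (any(abs(resid) > tol)) {
    worst <- rownames(E)[which.max(abs(resid))]
    stop("stoichiometry error: no exact solution; the ", worst,
         " balance cannot be closed with the given products", call. = FALSE)
  }
  coefs <- c(-1, x)
  names(coefs) <- colnames(E)
  structure(coefs, class = "reaction_stoichiometry", balances = balances)
}

#' @export
print.reaction_stoichiometry <- function(x, digits = 4, ...) {
  v <- unclass(x)
  lhs <- v[v < 0]; rhs <- v[v > 0]
  fmt <- function(s) paste(
    sprintf("%s %s", format(abs(s), digits = digits, trim = TRUE), names(s)),
    collapse = " + ")
  cat(fmt(lhs), "->", fmt(rhs), "\n")
  invisible(x)
}

#' Yields implied by the electron balance of acetate/N2O growth
#'
#' Closes the degree-of-reduction balance over growth of biomass (gamma 4.2
#' per C-mol under the default composition) on acetate (gamma 8 per mol, 2
#' C-mol) with N2O as the two-electron acceptor:
#' \deqn{8 = 8.4\,Y_{X/Ac} + 2\,Y_{N_2O/Ac}.}
#' At \eqn{Y_{X/Ac}=0} this reproduces the 4:1 catabolic N2O:acetate
#' stoichiometry.
#'
#' @param y_x_ac Biomass yield on acetate, C-mol/C-mol, in `[0, 8/8.4)`.
#' @param gamma_x Degree of reduction of biomass per C-mol (default 4.2).
#' @param n_x Biomass N content per C-mol (default 0.2), giving the ammonium
#'   yield under the assumed composition.
#' @return Named list with `y_n2o_ac` (mol N2O / mol acetate), `y_x_n2o`
#'   (C-mol biomass / mol N2O) and `y_nh4_x` (mol NH4+ / C-mol biomass).
#' @examples
#' predict_yields_from_electron_balance(0)      # y_n2o_ac = 4
#' predict_yields_from_electron_balance(0.15)   # y_n2o_ac = 3.37
#' @export
predict_yields_from_electron_balance <- function(y_x_ac, gamma_x = 4.2,
                                                 n_x = 0.2) {
  gamma_ac <- 8        # per mol acetate (2 C-mol, gamma 4 per C-mol)
  upper <- gamma_ac / (2 * gamma_x)
  if (!is.finite(y_x_ac) || y_x_ac < 0 || y_x_ac >= upper)
    stop("domain error: y_x_ac must lie in [0, ", format(upper), ")",
         call. = FALSE)
  y_n2o_ac <- (gamma_ac - 2 * gamma_x * y_x_ac) / 2
  list(y_n2o_ac = y_n2o_ac,
       y_x_n2o = 2 * y_x_ac / y_n2o_ac,
       y_nh4_x = n_x)
}
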