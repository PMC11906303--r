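#' Reduce conservation constraints to the measured species
#'
#' Partitions the conservation matrix `E = [E_m | E_u]` into measured and
#' unmeasured columns and eliminates the unmeasured rates: the rows of the
#' returned matrix are `K %*% E_m` where the rows of `K` form an orthonormal
#' basis of the left null space of `E_u`. The row space of the result is the
#' complete set of constraints testable from measured rates alone; a
#' zero-row matrix is a valid outcome (zero redundancy).
#'
#' For the acetate/N2O enrichment system (CO2, N2, H2O and H+ unmeasured)
#' exactly one reduced constraint survives: the degree-of-reduction balance at
#' nitrogen reference valence 0, with coefficients proportional to
#' (8, -2, 3, 4.8) on (acetate, N2O, NH4+, biomass).
#'
#' @param E Conservation matrix (rows = balances, columns = species), e.g.
#'   from [conservation_matrix()].
#' @param measured Logical vector over columns of `E` (or character vector of
#'   measured species names when `E` has column names).
#' @param tol Relative singular-value threshold for rank decisions
#'   (default `1e-10`).
#' @return Matrix with one column per measured species (possibly zero rows).
#' @export
reduce_constraints <- function(E, measured, tol = 1e-10) {
  stopifnot(is.matrix(E), nrow(E) >= 1L)
  if (is.character(measured)) {
    if (is.null(colnames(E)))
      stop("E needs column names to match measured species names", call. = FALSE)
    measured <- colnames(E) %in% measured
  }
  stopifnot(length(measured) == ncol(E))
  if (!any(measured))
    stop("at least one measured species is required", call. = FALSE)
  E_m <- E[, measured, drop = FALSE]
  E_u <- E[, !measured, drop = FALSE]
  if (ncol(E_u) == 0L) return(E_m)
  sv <- svd(E_u, nu = nrow(E_u))
  r <- sum(sv$d > tol * max(sv$d, 0) * max(dim(E_u)))
  if (r >= nrow(E_u)) {
    out <- matrix(0, 0L, ncol(E_m), dimnames = list(NULL, colnames(E_m)))
    return(out)
  }
  K <- t(sv$u[, (r + 1L):nrow(E_u), drop = FALSE])
  red <- K %*% E_m
  rownames(red) <- paste0("constraint_", seq_len(nrow(red)))
  red
}

#' Reconcile measured conversion rates under conservation constraints
#'
#' Adjusts measured steady-state conversion rates minimally — in the
#' Mahalanobis metric of their measurement variances — so the reduced
#' conservation constraints close exactly, and tests overall measurement
#' consistency with the chi-squared residual statistic. This is the classical
#' linear data-reconciliation solution: with diagonal covariance
#' \eqn{\Sigma = diag(sd^2)}, residual \eqn{\varepsilon = E r} and
#' \eqn{P = E \Sigma E^\top},
#' \deqn{\hat r = r - \Sigma E^\top P^{-1} \varepsilon, \qquad
#'       h = \varepsilon^\top P^{-1} \varepsilon \sim \chi^2_{dof}.}
#'
#' @param rates Either a data frame with columns `species`, `rate`, `sd`
#'   (production-positive, mmol/d) or a named numeric vector of rates (then
#'   supply `sd`).
#' @param system Optional `species_system`; when given, the constraint matrix
#'   is built from it ([conservation_matrix()] + [reduce_constraints()]) using
#'   its `measured` flags, and uniquely determined unmeasured rates are
#'   back-solved from the full balance set.
#' @param E Optional reduced constraint matrix acting on the measured species
#'   (columns in the order of `rates`); overrides `system`-derived
#'   constraints.
#' @param sd Named numeric vector of standard deviations when `rates` is a
#'   vector.
#' @param balances Balance set used when deriving constraints from `system`.
#' @param exempt Character vector of species to exclude from the balances
#'   (treated as unmeasured and unreported), e.g. `"nh4"` to exempt ammonium
#'   from the N balance when the biomass N content is in doubt.
#' @param tol Relative singular-value threshold for rank decisions.
#' @return An object of class `reconciliation`: list with elements
#'   `reconciled` (data frame species/rate/sd), `solved_unmeasured` (named
#'   vector, `NA` where not uniquely determined), `residual`, `h_statistic`,
#'   `dof`, `p_value`, `covariance_reconciled`, `E_reduced`, `adjustment`
#'   (standardized adjustments) and `dof_zero` flag.
#' @examples
#' sys <- n2o_species_system()
#' r <- data.frame(species = c("acetate", "n2o", "nh4", "biomass"),
#'                 rate = c(-10, -38, -0.3, 1.5),
#'                 sd = c(0.5, 2, 0.1, 0.1))
#' fit <- reconcile(r, system = sys)
#' fit$h_statistic
#' @export
reconcile <- function(rates, system = NULL, E = NULL, sd = NULL,
                      balances = c("C", "H", "O", "N", "charge"),
                      exempt = character(), tol = 1e-10) {
  if (is.numeric(rates)) {
    stopifnot(!is.null(names(rates)), !is.null(sd))
    rates <- data.frame(species = names(rates), rate = as.numeric(rates),
                        sd = as.numeric(sd[names(rates)]))
  }
  stopifnot(all(c("species", "rate", "sd") %in% names(rates)))
  r <- rates$rate
  s <- rates$sd
  names(r) <- names(s) <- rates$species
  if (!all(is.finite(r)) || !all(is.finite(s)) || any(s <= 0))
    stop("every measured species needs a finite rate and sd > 0", call. = FALSE)

  E_full <- NULL
  if (is.null(E)) {
    if (is.null(system))
      stop("supply either a species system or a reduced constraint matrix E",
           call. = FALSE)
    keep <- setdiff(names(system), exempt)
    system <- species_system(unname(system[keep]))
    E_full <- conservation_matrix(system, balances)
    meas_names <- names(system)[vapply(system, `[[`, logical(1), "measured")]
    missing_sp <- setdiff(meas_names, rates$species)
    if (length(missing_sp))
      stop("species absent from the rate table: ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    E <- reduce_constraints(E_full, measured = meas_names, tol = tol)
    E <- E[, rates$species[rates$species %in% meas_names], drop = FALSE]
    extra <- setdiff(rates$species, meas_names)
    if (length(extra))
      stop("rate table contains species not measured in the system: ",
           paste(extra, collapse = ", "), call. = FALSE)
  } else {
    E <- as.matrix(E)
    if (ncol(E) != nrow(rates))
      stop("E columns must match the measured species order", call. = FALSE)
    colnames(E) <- rates$species
  }

  Sigma <- diag(s^2, nrow = length(s))
  dof <- if (nrow(E)) qr(E)$rank else 0L

  if (dof == 0L) {
    out <- list(reconciled = rates, solved_unmeasured = numeric(),
                residual = numeric(0), h_statistic = NA_real_, dof = 0L,
                p_value = NA_real_,
                covariance_reconciled = Sigma,
                E_reduced = E, adjustment = setNames(rep(0, length(r)), names(r)),
                dof_zero = TRUE)
    class(out) <- "reconciliation"
    warning("zero redundancy: no testable constraint, rates returned unchanged",
            call. = FALSE)
    return(out)
  }

  eps <- as.vector(E %*% r)
  P <- E %*% Sigma %*% t(E)
  if (qr(P)$rank < nrow(P)) {
    g <- qr(t(E))
    dup <- setdiff(seq_len(nrow(E)), sort(g$pivot[seq_len(g$rank)]))
    stop("numerical error: singular constraint covariance; constraint(s) ",
         paste(if (length(dup)) rownames(E)[dup] else rownames(E),
               collapse = ", "),
         " are redundant or have zero propagated variance", call. = FALSE)
  }
  Pinv_eps <- solve(P, eps)
  r_hat <- r - as.vector(Sigma %*% t(E) %*% Pinv_eps)
  h <- sum(eps * Pinv_eps)
  h <- max(h, 0)
  cov_hat <- Sigma - Sigma %*% t(E) %*% solve(P, E %*% Sigma)
  dimnames(cov_hat) <- list(names(r), names(r))
  p <- stats::pchisq(h, df = dof, lower.tail = FALSE)

  sd_hat <- sqrt(pmax(diag(cov_hat), 0))
  adj <- (r - r_hat) / s

  solved <- numeric()
  if (!is.null(E_full)) {
    meas <- colnames(E_full) %in% names(r)
    E_u <- E_full[, !meas, drop = FALSE]
    if (ncol(E_u)) {
      qru <- qr(E_u)
      rhs <- -as.vector(E_full[, meas, drop = FALSE] %*% r_hat[colnames(E_full)[meas]])
      sol <- qr.coef(qru, rhs)
      sol[is.na(sol)] <- NA_real_
      names(sol) <- colnames(E_u)
      if (qru$rank < ncol(E_u)) sol[] <- NA_real_  # not uniquely determined
      solved <- sol
    }
  }

  out <- list(
    reconciled = data.frame(species = names(r), rate = unname(r_hat),
                            sd = unname(sd_hat)),
    solved_unmeasured = solved,
    residual = eps,
    h_statistic = h,
    dof = dof,
    p_value = p,
    covariance_reconciled = cov_hat,
    E_reduced = E,
    adjustment = adj,
    dof_zero = FALSE)
  class(out) <- "reconciliation"
  out
}

#' @export
print.reconciliation <- function(x, digits = 4, ...) {
  cat("Rate reconciliation under conservation constraints\n")
  cat(sprintf("  constraints: %d (dof %d)   h = %s   p = %s\n",
              nrow(x$E_reduced), x$dof,
              format(x$h_statistic, digits = digits),
              format(x$p_value, digits = digits)))
  df <- x$reconciled
  df$rate <- signif(df$rate, digits)
  df$sd <- signif(df$sd, digits)
  print(df, row.names = FALSE)
  if (length(x$solved_unmeasured)) {
    cat("  back-solved unmeasured rates:\n")
    print(signif(x$solved_unmeasured, digits))
  }
  invisible(x)
}

#' @export
summary.reconciliation <- function(object, alpha = 0.05, ...) {
  gt <- if (object$dof >= 1L) gross_error_test(object, alpha = alpha) else NULL
  structure(list(fit = object, gross_error = gt, alpha = alpha),
            class = "summary.reconciliation")
}

#' @export
print.summary.reconciliation <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$gross_error))
    cat(sprintf("  gross-error test (alpha = %g): %s — %s\n", x$alpha,
                if (x$gross_error$pass) "pass" else "FAIL",
                x$gross_error$message))
  invisible(x)
}

#' Chi-squared gross-error test of a reconciliation
#'
#' Fails when the upper-tail chi-squared probability of the residual statistic
#' falls below `alpha` (strict inequality), indicating that at least one
#' measurement is inconsistent with the conservation constraints beyond its
#' stated precision. The message names the species with the largest
#' standardized adjustment.
#'
#' @param result A `reconciliation` object.
#' @param alpha Significance level (default 0.05).
#' @return List with `pass` (logical), `p_value`, `h_statistic`, `message`.
#' @export
gross_error_test <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "reconciliation"))
  if (result$dof < 1L)
    stop("untestable: zero degrees of redundancy", call. = FALSE)
  pass <- !(result$p_value < alpha)
  worst <- names(which.max(abs(result$adjustment)))
  msg <- if (pass)
    sprintf("h = %.4g (p = %.4g): measurements consistent with the balances",
            result$h_statistic, result$p_value)
  else
    sprintf(paste0("h = %.4g (p = %.4g) < alpha: largest standardized ",
                   "adjustment on '%s' (%.2f sd)"),
            result$h_statistic, result$p_value, worst,
            abs(result$adjustment[[worst]]))
  list(pass = pass, p_value = result$p_value,
       h_statistic = result$h_statistic, message = msg)
}
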