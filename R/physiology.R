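#' Stoichiometric yields from reconciled conversion rates
#'
#' Computes the four yields of an acetate/N2O enrichment as ratios of
#' steady-state volumetric conversion rates, with unit conversions (acetate
#' mol to C-mol using its carbon number; biomass rate already on a C-mol
#' basis) and the linear error propagation used for ratio estimates:
#' \deqn{\sigma_Y = Y\sqrt{(\sigma_{num}/r_{num})^2 + (\sigma_{den}/r_{den})^2}.}
#' Only rate magnitudes enter the yields; the sign convention of the input
#' does not affect the result.
#'
#' @param rates A `reconciliation` object, or a data frame with columns
#'   `species`, `rate`, `sd` containing at least the species named in
#'   `roles`.
#' @param roles Named character vector mapping `donor`, `acceptor`,
#'   `n_source`, `biomass` to species names in `rates`.
#' @param donor_carbon Carbon atoms per mole of donor (mol to C-mol factor;
#'   default 2 for acetate).
#' @return A data frame of class `yield_set` with columns `yield`, `value`,
#'   `sd`, `units` for `y_x_ac` (C-mol/C-mol), `y_x_n2o` (C-mol/mol),
#'   `y_n2o_ac` (mol/mol) and `y_nh4_x` (mol/C-mol).
#' @examples
#' r <- data.frame(species = c("acetate", "n2o", "nh4", "biomass"),
#'                 rate = c(-10, -34.2, -0.6, 1.5),
#'                 sd = c(0.5, 2, 0.05, 0.1))
#' compute_yields(r)
#' @export
compute_yields <- function(rates,
                           roles = c(donor = "acetate", acceptor = "n2o",
                                     n_source = "nh4", biomass = "biomass"),
                           donor_carbon = 2) {
  if (inherits(rates, "reconciliation")) rates <- rates$reconciled
  stopifnot(all(c("species", "rate", "sd") %in% names(rates)))
  miss <- setdiff(unname(roles), rates$species)
  if (length(miss))
    stop("species absent from the rate table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  r <- rates$rate[match(roles, rates$species)]
  s <- rates$sd[match(roles, rates$species)]
  names(r) <- names(s) <- names(roles)

  ratio <- function(num, den, scale = 1) {
    if (r[[den]] == 0)
      stop("domain error: zero denominator rate (", roles[[den]], ")",
           call. = FALSE)
    y <- abs(r[[num]] / r[[den]]) * scale
    sdy <- y * sqrt((s[[num]] / r[[num]])^2 + (s[[den]] / r[[den]])^2)
    c(y, sdy)
  }
  y_x_ac   <- ratio("biomass", "donor", 1 / donor_carbon)
  y_x_n2o  <- ratio("biomass", "acceptor")
  y_n2o_ac <- ratio("acceptor", "donor")
  y_nh4_x  <- ratio("n_source", "biomass")

  out <- data.frame(
    yield = c("y_x_ac", "y_x_n2o", "y_n2o_ac", "y_nh4_x"),
    value = c(y_x_ac[1], y_x_n2o[1], y_n2o_ac[1], y_nh4_x[1]),
    sd    = c(y_x_ac[2], y_x_n2o[2], y_n2o_ac[2], y_nh4_x[2]),
    units = c("C-mol/C-mol", "C-mol/mol", "mol/mol", "mol/C-mol"))
  class(out) <- c("yield_set", class(out))
  out
}

#' @export
print.yield_set <- function(x, digits = 3, ...) {
  cat("Stoichiometric yields (ratio of reconciled conversion rates)\n")
  df <- as.data.frame(x)
  df$value <- signif(df$value, digits)
  df$sd <- signif(df$sd, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

# closed-form coefficient SEs and r^2 for an lm fit; avoids summary.lm's
# perfect-fit warning on noiseless inverse problems
ols_stats <- function(fit) {
  w <- fit$weights
  if (is.null(w)) w <- rep(1, length(fit$residuals))
  rss <- sum(w * fit$residuals^2)
  df <- fit$df.residual
  s2 <- if (df > 0) rss / df else 0
  R <- qr.R(fit$qr)                 # qr of sqrt(w)-scaled design
  XtXinv <- chol2inv(R)
  y <- fit$fitted.values + fit$residuals
  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  list(se = sqrt(pmax(diag(XtXinv) * s2, 0)),
       r_squared = if (tss > 0) 1 - rss / tss else 1)
}

#' Herbert-Pirt maintenance estimation across dilution rates
#'
#' Separates the biomass-specific substrate consumption rate into growth and
#' maintenance terms, \eqn{q_s = D/Y^{max} + m_s}, by regression of observed
#' growth yields against dilution rate. The default linearization regresses
#' `1/Y` on `1/D` by ordinary least squares, whose slope is the maintenance
#' coefficient `m_s` and whose intercept is `1/y_max`. Alternative forms:
#' `"qs"` regresses \eqn{q_s = D/Y} on `D` (intercept `m_s`, slope
#' `1/y_max`); `"direct"` fits \eqn{Y = D/(D/Y^{max} + m_s)} by nonlinear
#' least squares started from the reciprocal fit.
#'
#' @param D Dilution rates, 1/h (distinct, > 0), or a data frame with columns
#'   `D` and `Y` (optionally `Y_sd`).
#' @param Y Observed biomass yields on substrate, C-mol/C-mol (> 0).
#' @param Y_sd Optional yield standard deviations, used when
#'   `weights = "yield_sd"`.
#' @param form Regression form: `"reciprocal"` (default), `"qs"` or
#'   `"direct"`.
#' @param weights `"none"` (default, unweighted) or `"yield_sd"`
#'   (delta-method weights `Y^4 / Y_sd^2` on the reciprocal scale).
#' @return An object of class `pirt_fit` with elements `m_s`, `y_max`,
#'   `se_m_s`, `se_y_max`, `r_squared`, `n_points`, `form`, `fit` (the
#'   underlying model object) and `data`.
#' @examples
#' fit <- estimate_maintenance(D = c(0.006, 0.028, 0.089),
#'                             Y = c(0.15, 0.25, 0.27))
#' coef(fit)
#' @export
estimate_maintenance <- function(D, Y = NULL, Y_sd = NULL,
                                 form = c("reciprocal", "qs", "direct"),
                                 weights = c("none", "yield_sd")) {
  form <- match.arg(form)
  weights <- match.arg(weights)
  if (is.data.frame(D)) {
    Y_sd <- D$Y_sd
    Y <- D$Y
    D <- D$D
  }
  if (length(unique(D)) < 2L)
    stop("degenerate design: need at least 2 distinct dilution rates",
         call. = FALSE)
  if (any(!is.finite(D)) || any(D <= 0))
    stop("domain error: dilution rates must be positive", call. = FALSE)
  if (any(!is.finite(Y)) || any(Y <= 0))
    stop("domain error: yields must be positive", call. = FALSE)
  w <- NULL
  if (weights == "yield_sd") {
    if (is.null(Y_sd) || any(Y_sd <= 0))
      stop("yield_sd weighting requires positive Y_sd", call. = FALSE)
    w <- Y^4 / Y_sd^2
  }
  dat <- data.frame(D = D, Y = Y)

  if (form == "reciprocal") {
    fit <- stats::lm(I(1 / Y) ~ I(1 / D), data = dat, weights = w)
    cf <- stats::coef(fit)
    st <- ols_stats(fit)
    m_s <- unname(cf[2]); y_max <- 1 / unname(cf[1])
    se_m_s <- st$se[2]
    se_y_max <- st$se[1] / cf[1]^2          # delta method on 1/intercept
    r2 <- st$r_squared
  } else if (form == "qs") {
    fit <- stats::lm(I(D / Y) ~ D, data = dat, weights = w)
    cf <- stats::coef(fit)
    st <- ols_stats(fit)
    m_s <- unname(cf[1]); y_max <- 1 / unname(cf[2])
    se_m_s <- st$se[1]
    se_y_max <- st$se[2] / cf[2]^2
    r2 <- st$r_squared
  } else {
    start <- estimate_maintenance(D, Y, form = "reciprocal")
    fit <- stats::nls(Y ~ D / (D / y_max + m_s), data = dat,
                      start = list(y_max = start$y_max, m_s = start$m_s),
                      weights = w,
                      control = stats::nls.control(scaleOffset = 1))
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    m_s <- unname(cf["m_s"]); y_max <- unname(cf["y_max"])
    se_m_s <- unname(se["m_s"]); se_y_max <- unname(se["y_max"])
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((Y - mean(Y))^2)
  }

  structure(list(m_s = m_s, y_max = y_max, se_m_s = se_m_s,
                 se_y_max = unname(se_y_max), r_squared = r2,
                 n_points = length(D), form = form, weights = weights,
                 fit = fit, data = dat),
            class = "pirt_fit")
}

#' @export
print.pirt_fit <- function(x, digits = 4, ...) {
  cat("Herbert-Pirt maintenance fit (", x$form, " form, ", x$n_points,
      " points)\n", sep = "")
  cat(sprintf("  m_s   = %s +/- %s  C-mol substrate (C-mol X)^-1 h^-1\n",
              format(x$m_s, digits = digits),
              format(x$se_m_s, digits = digits)))
  cat(sprintf("  y_max = %s +/- %s  C-mol/C-mol\n",
              format(x$y_max, digits = digits),
              format(x$se_y_max, digits = digits)))
  cat(sprintf("  r^2   = %s\n", format(x$r_squared, digits = digits)))
  invisible(x)
}

#' @export
coef.pirt_fit <- function(object, ...) {
  c(m_s = object$m_s, y_max = object$y_max)
}

#' @export
summary.pirt_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying regression:\n")
  print(summary(object$fit))
  invisible(object)
}

#' Predicted yields at new dilution rates
#'
#' @param object A `pirt_fit`.
#' @param newdata Data frame with column `D`, or numeric vector of dilution
#'   rates; defaults to the fitted data.
#' @param ... Unused.
#' @return Predicted yields Y(D) = D / (D / y_max + m_s).
#' @export
predict.pirt_fit <- function(object, newdata = NULL, ...) {
  D <- if (is.null(newdata)) object$data$D
       else if (is.data.frame(newdata)) newdata$D else newdata
  D / (D / object$y_max + object$m_s)
}

#' @export
residuals.pirt_fit <- function(object, ...) {
  object$data$Y - predict(object)
}

#' Dissolved gas concentration from Henry's law
#'
#' @param partial_pressure Partial pressure in the gas phase, Pa (>= 0).
#' @param henry_constant Henry solubility, mmol/(L Pa); the default
#'   `2.4e-4` is the N2O value at the 20 degree C operating temperature.
#' @return Dissolved concentration, mmol/L.
#' @examples
#' dissolved_gas(1592)  # ~0.382 mmol/L, i.e. 382 uM
#' @export
dissolved_gas <- function(partial_pressure, henry_constant = 2.4e-4) {
  if (any(partial_pressure < 0) || any(henry_constant < 0))
    stop("domain error: pressure and Henry constant must be non-negative",
         call. = FALSE)
  henry_constant * partial_pressure
}

#' Biomass dilution rate from solids retention time
#'
#' In a membrane bioreactor the solids retention time sets the biomass
#' dilution rate, `D = 1 / (24 * SRT)` with SRT in days and D in 1/h.
#'
#' @param srt Solids retention time, days (> 0).
#' @return Dilution rate, 1/h.
#' @examples
#' dilution_rate_from_srt(6.9)  # 0.00604 -> the operating D of 0.006 1/h
#' @export
dilution_rate_from_srt <- function(srt) {
  if (any(!is.finite(srt)) || any(srt <= 0))
    stop("domain error: SRT must be positive", call. = FALSE)
  1 / (24 * srt)
}
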