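#' Validate a batch depletion series
#'
#' A batch series holds the timed concentration measurements of one or more
#' replicate bottles plus the (common) biomass concentration of the assay.
#' At least four time points per replicate are required for the slope
#' regression; times must be strictly increasing within a replicate.
#'
#' @param time Sampling times, h.
#' @param conc Concentrations, mmol/L (>= 0).
#' @param replicate Replicate (bottle) identifier; default a single bottle.
#' @param biomass Biomass concentration of the assay, g VSS/L (> 0).
#' @param biomass_sd Its standard deviation (>= 0).
#' @return A data frame of class `batch_series` with attributes `biomass` and
#'   `biomass_sd`.
#' @export
batch_series <- function(time, conc, replicate = 1L, biomass, biomass_sd = 0) {
  df <- data.frame(time = time, conc = conc,
                   replicate = rep_len(replicate, length(time)))
  if (any(!is.finite(df$time)) || any(!is.finite(df$conc)))
    stop("input error: non-finite time or concentration", call. = FALSE)
  if (any(df$conc < 0))
    stop("input error: negative concentration", call. = FALSE)
  if (!is.finite(biomass) || biomass <= 0)
    stop("domain error: biomass concentration must be positive", call. = FALSE)
  for (rep_id in unique(df$replicate)) {
    t_r <- df$time[df$replicate == rep_id]
    if (length(t_r) < 4L)
      stop("insufficient data: at least four concentration points per ",
           "replicate are required (replicate ", rep_id, " has ",
           length(t_r), ")", call. = FALSE)
    if (any(diff(t_r) <= 0))
      stop("input error: times must be strictly increasing within replicate ",
           rep_id, call. = FALSE)
  }
  structure(df, biomass = biomass, biomass_sd = biomass_sd,
            class = c("batch_series", "data.frame"))
}

#' Volumetric consumption rate from a batch depletion series
#'
#' Ordinary least-squares slope of concentration versus time within each
#' replicate bottle, sign-flipped so that consumption is positive, with the
#' regression standard error.
#'
#' @param series A [batch_series()], or a data frame with columns `time`,
#'   `conc` and optionally `replicate`.
#' @return A data frame of class `batch_rate` with one row per replicate:
#'   `replicate`, `rate` (mmol/L/h, consumption positive), `se`,
#'   `r_squared`, `n`.
#' @examples
#' s <- batch_series(time = 0:3, conc = c(1.1, 0.9, 0.7, 0.5), biomass = 0.9)
#' fit_volumetric_rate(s)
#' @export
fit_volumetric_rate <- function(series) {
  stopifnot(is.data.frame(series), all(c("time", "conc") %in% names(series)))
  if (is.null(series$replicate)) series$replicate <- 1L
  out <- do.call(rbind, lapply(split(series, series$replicate), function(d) {
    if (nrow(d) < 4L)
      stop("insufficient data: at least four concentration points are ",
           "required", call. = FALSE)
    if (any(diff(d$time) <= 0))
      stop("input error: times must be strictly increasing", call. = FALSE)
    fit <- stats::lm(conc ~ time, data = d)
    st <- ols_stats(fit)
    data.frame(replicate = d$replicate[1],
               rate = -unname(stats::coef(fit)[2]),
               se = st$se[2],
               r_squared = st$r_squared,
               n = nrow(d))
  }))
  rownames(out) <- NULL
  class(out) <- c("batch_rate", class(out))
  out
}

#' @export
print.batch_rate <- function(x, digits = 4, ...) {
  cat("Volumetric batch rates (consumption positive, mmol/L/h)\n")
  df <- as.data.frame(x)
  df$rate <- signif(df$rate, digits)
  df$se <- signif(df$se, digits)
  df$r_squared <- signif(df$r_squared, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Biomass-specific rate from replicate volumetric rates
#'
#' Averages the per-bottle volumetric rates, divides by the biomass
#' concentration of the assay, and propagates the replicate scatter and the
#' biomass uncertainty linearly:
#' \deqn{\sigma_q = q\sqrt{(\sigma_r/r)^2 + (\sigma_X/X)^2}.}
#' With a single replicate the regression standard error of its slope stands
#' in for the across-bottle scatter.
#'
#' @param rates A `batch_rate` data frame (from [fit_volumetric_rate()]) or a
#'   numeric vector of volumetric rates, mmol/L/h.
#' @param biomass Biomass concentration (> 0) in g VSS/L, or in C-mmol/L when
#'   `unit = "per_cmol"` inputs are already converted.
#' @param biomass_sd Standard deviation of the biomass concentration.
#' @param unit Unit tag of the result: `"per_gVSS"` (mmol g_VSS^-1 h^-1,
#'   default) or `"per_cmol"` (mmol C-mol_X^-1 h^-1; converts `biomass` from
#'   g VSS/L using `vss_per_cmol`).
#' @param vss_per_cmol Grams VSS per C-mol biomass (default 24.6 for
#'   CH1.8O0.5N0.2).
#' @return An object of class `specific_rate`: list with `q`, `sd`,
#'   `volumetric_rate`, `volumetric_sd`, `n_replicates`, `unit`.
#' @examples
#' specific_rate(c(0.95, 1.05), biomass = 2.0, biomass_sd = 0.2)
#' @export
specific_rate <- function(rates, biomass, biomass_sd = 0,
                          unit = c("per_gVSS", "per_cmol"),
                          vss_per_cmol = 24.6) {
  unit <- match.arg(unit)
  if (!is.finite(biomass) || biomass <= 0)
    stop("domain error: biomass concentration must be positive", call. = FALSE)
  if (inherits(rates, "batch_rate") || is.data.frame(rates)) {
    r_i <- rates$rate
    se_single <- rates$se
  } else {
    r_i <- as.numeric(rates)
    se_single <- NA_real_
  }
  if (length(r_i) < 1L)
    stop("need at least one replicate rate", call. = FALSE)
  r <- mean(r_i)
  sr <- if (length(r_i) > 1L) stats::sd(r_i) else
    if (all(is.finite(se_single))) se_single[1] else 0
  # per_cmol: biomass g VSS/L -> C-mol/L, so q = r/X is mmol (C-mol X)^-1 h^-1
  X <- if (unit == "per_cmol") biomass / vss_per_cmol else biomass
  sX <- if (unit == "per_cmol") biomass_sd / vss_per_cmol else biomass_sd
  q <- r / X
  rel <- sqrt((if (r != 0) sr / r else 0)^2 + (sX / X)^2)
  structure(list(q = q, sd = abs(q) * rel, volumetric_rate = r,
                 volumetric_sd = sr, n_replicates = length(r_i), unit = unit),
            class = "specific_rate")
}

#' @export
print.specific_rate <- function(x, digits = 4, ...) {
  u <- if (x$unit == "per_gVSS") "mmol g_VSS^-1 h^-1" else
    "mmol (C-mol X)^-1 h^-1"
  cat(sprintf("q = %s +/- %s %s  (volumetric %s +/- %s mmol/L/h, %d replicate%s)\n",
              format(x$q, digits = digits), format(x$sd, digits = digits), u,
              format(x$volumetric_rate, digits = digits),
              format(x$volumetric_sd, digits = digits),
              x$n_replicates, if (x$n_replicates == 1) "" else "s"))
  invisible(x)
}
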