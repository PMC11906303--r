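#' Ground truth for a synthetic chemostat experiment
#'
#' Bundles the Herbert-Pirt parameters, operating conditions and noise model
#' from which [generate_chemostat_dataset()] simulates steady-state
#' conversion-rate measurements. The presets mirror the two enrichment
#' regimes of an acetate-fed N2O-respiring membrane bioreactor: `"N2Oexc"`
#' (acetate-limited, N2O in excess; feed loads 31.6 / 382 mmol/d,
#' maintenance 0.019) and `"N2Olim"` (N2O-limited; loads 46.1 / 84 mmol/d,
#' maintenance 0.008), both spanning dilution rates from the 0.006 1/h
#' membrane-reactor operation up to the ~0.09 1/h literature chemostats, with
#' y_max 0.29 C-mol/C-mol and 5 % measurement noise on every rate.
#'
#' @param preset `"N2Oexc"` or `"N2Olim"`; individual arguments override
#'   preset values.
#' @param y_max Maximum biomass yield on acetate, C-mol/C-mol, in
#'   `(0, 8/8.4)`.
#' @param m_s Maintenance coefficient, C-mol Ac (C-mol X)^-1 h^-1 (>= 0).
#' @param D Dilution-rate levels, 1/h.
#' @param acetate_load,n2o_load Influent loads, mmol/d.
#' @param limiting Which feed sets the consumed amount: `"acetate"` or
#'   `"n2o"`.
#' @param cv Measurement coefficient of variation applied to every rate.
#' @param n_x Biomass N content per C-mol (ammonium uptake stoichiometry).
#' @return List of class `chemostat_ground_truth`.
#' @export
chemostat_ground_truth <- function(preset = c("N2Oexc", "N2Olim"),
                                   y_max = 0.29, m_s = NULL, D = NULL,
                                   acetate_load = NULL, n2o_load = NULL,
                                   limiting = NULL, cv = 0.05, n_x = 0.2) {
  preset <- match.arg(preset)
  p <- switch(preset,
    N2Oexc = list(m_s = 0.019, D = c(0.006, 0.028, 0.089),
                  acetate_load = 31.6, n2o_load = 382, limiting = "acetate"),
    N2Olim = list(m_s = 0.008, D = c(0.006, 0.027, 0.086),
                  acetate_load = 46.1, n2o_load = 84, limiting = "n2o"))
  if (is.null(m_s)) m_s <- p$m_s
  if (is.null(D)) D <- p$D
  if (is.null(acetate_load)) acetate_load <- p$acetate_load
  if (is.null(n2o_load)) n2o_load <- p$n2o_load
  if (is.null(limiting)) limiting <- p$limiting
  if (!is.finite(y_max) || y_max <= 0 || y_max >= 8 / 8.4)
    stop("domain error: y_max must lie in (0, 8/8.4)", call. = FALSE)
  if (m_s < 0 || cv < 0)
    stop("domain error: m_s and cv must be non-negative", call. = FALSE)
  if (any(D <= 0) || acetate_load < 0 || n2o_load < 0)
    stop("domain error: D and loads must be positive", call. = FALSE)
  structure(list(preset = preset, y_max = y_max, m_s = m_s, D = D,
                 acetate_load = acetate_load, n2o_load = n2o_load,
                 limiting = match.arg(limiting, c("acetate", "n2o")),
                 cv = cv, n_x = n_x),
            class = "chemostat_ground_truth")
}

#' Simulate steady-state chemostat rate measurements
#'
#' For each dilution rate the observed yield follows the Herbert-Pirt law
#' \eqn{Y(D) = D/(D/Y^{max} + m_s)}; the true conversion rates are built from
#' fixed stoichiometry (acetate consumption from the limiting feed, biomass
#' production from the yield, N2O consumption closing the electron balance
#' at 2 electrons per N2O, ammonium uptake from the biomass N content), so
#' every conservation balance closes exactly before noise. Gaussian
#' measurement noise with the stated coefficient of variation is then applied
#' to each rate independently.
#'
#' @param truth A [chemostat_ground_truth()].
#' @param seed Optional integer seed (bit-reproducible output).
#' @return List with `rates` (list of per-D data frames with columns
#'   `species`, `rate`, `sd`, production-positive, mmol/d), `true_rates`
#'   (noiseless counterparts), `true_yields` (data frame `D`, `Y`), and
#'   `truth`.
#' @examples
#' tr <- chemostat_ground_truth("N2Oexc", cv = 0)
#' d <- generate_chemostat_dataset(tr, seed = 1)
#' d$true_yields
#' @export
generate_chemostat_dataset <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "chemostat_ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  gamma_ac <- 8; gamma_x <- 4.2
  per_d <- lapply(truth$D, function(D) {
    Y <- D / (D / truth$y_max + truth$m_s)
    ac <- if (truth$limiting == "acetate") truth$acetate_load
          else 2 * truth$n2o_load / (gamma_ac - 2 * gamma_x * Y)
    x <- Y * 2 * ac                                   # C-mmol/d
    n2o <- (gamma_ac * ac - gamma_x * x) / 2          # mmol/d
    nh4 <- truth$n_x * x
    r <- c(acetate = -ac, n2o = -n2o, nh4 = -nh4, biomass = x)
    sd <- truth$cv * abs(r)
    obs <- r + stats::rnorm(length(r), 0, sd)
    list(true = data.frame(species = names(r), rate = unname(r),
                           sd = unname(sd)),
         obs = data.frame(species = names(r), rate = unname(obs),
                          sd = unname(sd)),
         Y = Y)
  })
  list(rates = lapply(per_d, `[[`, "obs"),
       true_rates = lapply(per_d, `[[`, "true"),
       true_yields = data.frame(D = truth$D,
                                Y = vapply(per_d, `[[`, numeric(1), "Y")),
       truth = truth)
}

#' Simulate a linear batch depletion series
#'
#' Linear substrate depletion from an initial concentration at the volumetric
#' rate `q_true * biomass`, with additive Gaussian noise, truncated at zero.
#'
#' @param q_true True biomass-specific consumption rate,
#'   mmol g_VSS^-1 h^-1 (> 0).
#' @param biomass Biomass concentration, g VSS/L (> 0).
#' @param n_points Number of time points (>= 4).
#' @param dt Sampling interval, h (> 0).
#' @param noise_sd Additive concentration noise, mmol/L (>= 0).
#' @param c0 Initial concentration, mmol/L (default 1.1, the nitrite batch
#'   assay's starting level).
#' @param n_replicates Number of replicate bottles.
#' @param seed Optional integer seed.
#' @return A [batch_series()].
#' @export
generate_batch_series <- function(q_true, biomass, n_points = 8, dt = 0.25,
                                  noise_sd = 0.02, c0 = 1.1,
                                  n_replicates = 1, seed = NULL) {
  if (n_points < 4)
    stop("domain error: at least four time points are required", call. = FALSE)
  if (q_true <= 0 || biomass <= 0 || dt <= 0 || c0 <= 0 || noise_sd < 0)
    stop("domain error: parameters must be positive (noise_sd >= 0)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tt <- (seq_len(n_points) - 1) * dt
  one <- function(rep_id) {
    conc <- c0 - q_true * biomass * tt +
      stats::rnorm(n_points, 0, noise_sd)
    data.frame(time = tt, conc = pmax(conc, 0), replicate = rep_id)
  }
  df <- do.call(rbind, lapply(seq_len(n_replicates), one))
  batch_series(df$time, df$conc, df$replicate, biomass = biomass)
}

#' Simulate multinomial spectral counts from a known proteome
#'
#' Draws per-injection spectral counts from a multinomial whose class
#' probabilities are proportional to (mass fraction x molecular weight), so
#' that the molecular-weight-normalized shares of
#' [normalize_spectral_counts()] recover the mass fractions in expectation.
#' Optional decoy-like contaminants carry a single unique peptide (and are
#' removed by the default detection filter); real proteins draw 2-6 unique
#' peptides.
#'
#' @param fractions True proteome mass fractions (non-negative, sum to 1;
#'   names become protein ids).
#' @param mw Molecular weights, Da; by default drawn log-normally around
#'   35 kDa.
#' @param depth Spectra per injection (default 20000, a typical per-sample
#'   MS2 yield).
#' @param n_injections Number of injections (default 4).
#' @param contaminant_fraction Total mass fraction diverted to
#'   single-peptide contaminants (default 0).
#' @param n_contaminants Number of contaminant proteins.
#' @param seed Optional integer seed.
#' @return List with `table` (a [spectral_count_table()]) and `truth`
#'   (data frame `protein_id`, `fraction`, `contaminant`).
#' @export
generate_spectral_counts <- function(fractions, mw = NULL, depth = 20000,
                                     n_injections = 4,
                                     contaminant_fraction = 0,
                                     n_contaminants = 0, seed = NULL) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("domain error: fractions must be non-negative and sum to 1",
         call. = FALSE)
  if (depth < 1) stop("domain error: depth must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(fractions)
  ids <- if (!is.null(names(fractions))) names(fractions)
         else sprintf("prot_%03d", seq_len(n))
  if (n_contaminants > 0 && contaminant_fraction > 0) {
    f_cont <- rep(contaminant_fraction / n_contaminants, n_contaminants)
    fractions <- c(fractions * (1 - contaminant_fraction), f_cont)
    ids <- c(ids, sprintf("contam_%03d", seq_len(n_contaminants)))
  }
  m <- length(fractions)
  if (is.null(mw)) mw <- stats::rlnorm(m, log(35000), 0.4)
  p <- fractions * mw
  counts <- stats::rmultinom(n_injections, size = depth, prob = p / sum(p))
  colnames(counts) <- paste0("inj_", seq_len(n_injections))
  contaminant <- grepl("^contam_", ids)
  up <- ifelse(contaminant, 1L,
               sample(2:6, m, replace = TRUE))
  list(table = spectral_count_table(ids, mw, up, counts),
       truth = data.frame(protein_id = ids, fraction = fractions,
                          contaminant = contaminant))
}

#' Simulate per-contig mapped read counts for a set of MAGs
#'
#' Per-contig read counts are Poisson with mean proportional to
#' (organism abundance x contig length); the remainder `1 - sum(abundances)`
#' is assigned to an unbinned pseudo-bin. With this sampling law
#' [mag_normalized_abundance()] recovers the abundances and
#' [mag_read_fraction()] recovers the abundance-times-genome-size read
#' shares.
#'
#' @param abundances Named vector of true organism abundances per MAG
#'   (non-negative, sum <= 1).
#' @param contig_lengths Data frame with columns `contig_id`, `mag_id`,
#'   `length_bp` covering every MAG in `abundances` (and optionally an
#'   `"unbinned"` pool; if absent and the abundances sum below 1, a single
#'   unbinned contig of the median MAG size is added).
#' @param total_reads Expected total read count (>= 0).
#' @param seed Optional integer seed.
#' @return A contig map data frame (`contig_id`, `mag_id`, `length_bp`,
#'   `mapped_reads`) ready for [mag_read_fraction()] /
#'   [mag_normalized_abundance()].
#' @export
generate_mag_reads <- function(abundances, contig_lengths, total_reads,
                               seed = NULL) {
  if (any(abundances < 0) || sum(abundances) > 1 + 1e-8)
    stop("domain error: abundances must be non-negative with sum <= 1",
         call. = FALSE)
  stopifnot(all(c("contig_id", "mag_id", "length_bp") %in%
                  names(contig_lengths)))
  if (!is.null(seed)) set.seed(seed)
  rem <- 1 - sum(abundances)
  a <- abundances
  if (rem > 1e-8 && !"unbinned" %in% contig_lengths$mag_id) {
    contig_lengths <- rbind(
      contig_lengths[, c("contig_id", "mag_id", "length_bp")],
      data.frame(contig_id = "unbinned_pool", mag_id = "unbinned",
                 length_bp = stats::median(tapply(contig_lengths$length_bp,
                                                  contig_lengths$mag_id,
                                                  sum))))
  }
  if (rem > 1e-8) a <- c(a, unbinned = rem)
  miss <- setdiff(names(a), contig_lengths$mag_id)
  if (length(miss))
    stop("no contigs for MAG(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cl <- contig_lengths[contig_lengths$mag_id %in% names(a), , drop = FALSE]
  wt <- a[cl$mag_id] * cl$length_bp
  mean_reads <- if (sum(wt) > 0) total_reads * wt / sum(wt) else wt * 0
  cl$mapped_reads <- if (total_reads > 0)
    stats::rpois(nrow(cl), mean_reads) else 0L
  rownames(cl) <- NULL
  cl
}
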