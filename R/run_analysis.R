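#' Run a named analysis from a validated configuration
#'
#' The scriptable front end of the package: dispatches one of the pipeline
#' analyses from a configuration list (or YAML file), writes tidy TSV
#' outputs plus a run log echoing the resolved configuration and package
#' version, and returns the result object. Outputs are deterministic: the
#' `simulate` task takes its seed from the configuration, so identical
#' configurations produce byte-identical files.
#'
#' Tasks and their required configuration fields:
#' \describe{
#'   \item{`reconcile`}{`rates` (path); optional `species_config`, `exempt`,
#'     `alpha`.}
#'   \item{`yields`}{`rates` (path, reconciled first); optional as above.}
#'   \item{`maintenance`}{`yields` (path with columns `D`, `Y` or the
#'     packaged `regime`-keyed table) and optional `regime`, `form`,
#'     `weights`.}
#'   \item{`batch-rate`}{`batch` (path); optional `unit`.}
#'   \item{`proteome-quant`}{`spectral_counts` (path), `protein_map` (path);
#'     optional `fasta`, `min_unique_peptides`, `min_injections`.}
#'   \item{`mag-abundance`}{`contig_map` (path), `total_reads`.}
#'   \item{`simulate`}{`preset`, `seed`.}
#' }
#'
#' @param task One of `"reconcile"`, `"yields"`, `"maintenance"`,
#'   `"batch-rate"`, `"proteome-quant"`, `"mag-abundance"`, `"simulate"`.
#' @param config Named list, or path to a YAML file with these fields.
#' @param output_dir Directory for outputs (created if needed); overrides
#'   `config$output_dir`; default a temporary directory.
#' @return The analysis result object, invisibly, with attribute `"outputs"`
#'   listing the files written.
#' @export
run_analysis <- function(task = c("reconcile", "yields", "maintenance",
                                  "batch-rate", "proteome-quant",
                                  "mag-abundance", "simulate"),
                         config = list(), output_dir = NULL) {
  task <- match.arg(task)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  out_dir <- output_dir %||% config$output_dir %||% tempfile("chemobalance_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  need <- function(fields) {
    miss <- fields[vapply(fields, function(f) is.null(config[[f]]),
                          logical(1))]
    if (length(miss))
      stop("schema violation for task '", task, "': missing field(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (f in fields) {
      v <- config[[f]]
      if (is.character(v) && length(v) == 1L && grepl("[/.]", v) &&
          f %in% c("rates", "yields", "batch", "spectral_counts",
                   "protein_map", "contig_map", "fasta", "species_config") &&
          !file.exists(v))
        stop("missing file for '", f, "': ", v, call. = FALSE)
    }
  }
  system <- if (!is.null(config$species_config))
    read_species_config(config$species_config) else n2o_species_system()
  outputs <- character()
  emit <- function(df, name, params = list()) {
    p <- file.path(out_dir, name)
    write_tsv_commented(df, p, params)
    outputs <<- c(outputs, p)
  }

  result <- switch(task,
    "reconcile" = {
      need("rates")
      rt <- read_rate_table(config$rates)
      fit <- reconcile(rt, system = system,
                       exempt = config$exempt %||% character())
      emit(fit$reconciled, "reconciled_rates.tsv",
           list(units = "mmol/d, production-positive",
                h_statistic = fit$h_statistic, dof = fit$dof,
                p_value = fit$p_value))
      fit
    },
    "yields" = {
      need("rates")
      rt <- read_rate_table(config$rates)
      fit <- reconcile(rt, system = system,
                       exempt = config$exempt %||% character())
      ys <- compute_yields(fit)
      emit(as.data.frame(ys), "yields.tsv",
           list(h_statistic = fit$h_statistic, p_value = fit$p_value))
      ys
    },
    "maintenance" = {
      need("yields")
      df <- if (identical(config$yields, "packaged"))
        enrichment_yield_table() else read_tsv_commented(config$yields)
      if (!is.null(config$regime) && "regime" %in% names(df))
        df <- df[df$regime == config$regime, , drop = FALSE]
      if (!"D" %in% names(df))
        stop("malformed yield table: need column D", call. = FALSE)
      Y <- if ("Y" %in% names(df)) df$Y else df$y_x_ac
      fits <- estimate_maintenance(
        df$D, Y, form = config$form %||% "reciprocal",
        weights = config$weights %||% "none")
      emit(data.frame(parameter = c("m_s", "y_max"),
                      value = c(fits$m_s, fits$y_max),
                      se = c(fits$se_m_s, fits$se_y_max),
                      units = c("C-mol Ac (C-mol X)^-1 h^-1", "C-mol/C-mol")),
           "maintenance.tsv",
           list(form = fits$form, r_squared = fits$r_squared,
                n_points = fits$n_points))
      fits
    },
    "batch-rate" = {
      need("batch")
      bs <- read_batch_table(config$batch)
      vr <- fit_volumetric_rate(bs)
      q <- specific_rate(vr, biomass = attr(bs, "biomass"),
                         biomass_sd = attr(bs, "biomass_sd"),
                         unit = config$unit %||% "per_gVSS")
      emit(data.frame(q = q$q, q_sd = q$sd,
                      volumetric_rate = q$volumetric_rate,
                      volumetric_sd = q$volumetric_sd,
                      n_replicates = q$n_replicates, unit = q$unit),
           "specific_rate.tsv", list())
      q
    },
    "proteome-quant" = {
      need(c("spectral_counts", "protein_map"))
      tab <- read_spectral_counts(config$spectral_counts,
                                  fasta = config$fasta)
      shares <- normalize_spectral_counts(tab)
      ab <- filter_and_average(
        shares, tab,
        min_unique_peptides = config$min_unique_peptides %||% 2,
        min_injections = config$min_injections %||% 2)
      pm <- read_tsv_commented(config$protein_map)
      frac <- mag_proteome_fraction(ab, pm)
      emit(ab, "protein_abundance.tsv",
           list(min_unique_peptides = config$min_unique_peptides %||% 2,
                min_injections = config$min_injections %||% 2))
      emit(frac, "mag_proteome_fraction.tsv", list())
      frac
    },
    "mag-abundance" = {
      need(c("contig_map", "total_reads"))
      cm <- read_contig_map(config$contig_map)
      rf <- mag_read_fraction(cm, total_reads = config$total_reads)
      na <- mag_normalized_abundance(cm)
      emit(rf$per_mag, "mag_read_fraction.tsv",
           list(total_reads = config$total_reads,
                binned_pct = rf$binned_pct))
      emit(na, "mag_normalized_abundance.tsv", list())
      list(read_fraction = rf, normalized_abundance = na)
    },
    "simulate" = {
      need(c("preset", "seed"))
      tr <- chemostat_ground_truth(config$preset,
                                   cv = config$cv %||% 0.05)
      sim <- generate_chemostat_dataset(tr, seed = as.integer(config$seed))
      for (i in seq_along(sim$rates))
        emit(sim$rates[[i]], sprintf("simulated_rates_D%d.tsv", i),
             list(D = tr$D[i], preset = tr$preset, seed = config$seed))
      emit(sim$true_yields, "simulated_true_yields.tsv",
           list(preset = tr$preset))
      sim
    })

  log <- c(sprintf("chemobalance %s",
                   as.character(utils::packageVersion("chemobalance"))),
           sprintf("task: %s", task), "config:",
           strsplit(yaml::as.yaml(config), "\n")[[1]])
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log, log_path)
  outputs <- c(outputs, log_path)
  attr(result, "outputs") <- outputs
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
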