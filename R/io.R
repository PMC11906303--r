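#' Write a tidy TSV with a commented header block
#'
#' Tables are UTF-8, tab-separated, with `#`-prefixed header lines carrying
#' key-value metadata (units, parameters, software version) — units errors
#' being the dominant failure mode in this domain, every table carries its
#' own. Numbers are written with 15 significant digits so a write/read
#' round trip is lossless well beyond 12 significant digits.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param params Named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, params = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(sprintf("# chemobalance %s",
                   as.character(utils::packageVersion("chemobalance"))),
           vapply(names(params), function(k)
             sprintf("# %s: %s", k, paste(format(params[[k]]), collapse = " ")),
             character(1)))
  writeLines(hdr, con)
  y <- x
  for (j in seq_along(y))
    if (is.numeric(y[[j]]))
      y[[j]] <- formatC(y[[j]], digits = 15, format = "g")
  utils::write.table(y, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented-header TSV
#'
#' @param path Input path.
#' @return Data frame; the parsed `# key: value` header lines are attached as
#'   attribute `"params"` (named character vector).
#' @export
read_tsv_commented <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  kv <- kv[lengths(kv) == 3]
  params <- stats::setNames(vapply(kv, `[[`, character(1), 3L),
                            trimws(vapply(kv, `[[`, character(1), 2L)))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          encoding = "UTF-8")
  attr(df, "params") <- params
  df
}

#' Read a measured-rate table
#'
#' Expects columns `species`, `rate`, `sd` (mmol/d, production-positive).
#'
#' @param path TSV path.
#' @return Data frame ready for [reconcile()].
#' @export
read_rate_table <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("species", "rate", "sd")
  if (!all(need %in% names(df)))
    stop("malformed rate table ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df
}

#' Read a long-format batch series table
#'
#' Expects columns `time_h`, `conc_mM`, `replicate` plus header parameters
#' `biomass_gVSS_L` (required) and `biomass_sd` (optional).
#'
#' @param path TSV path.
#' @return A [batch_series()].
#' @export
read_batch_table <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("time_h", "conc_mM", "replicate")
  if (!all(need %in% names(df)))
    stop("malformed batch table ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  p <- attr(df, "params")
  if (is.na(p["biomass_gVSS_L"]))
    stop("malformed batch table ", path,
         ": missing '# biomass_gVSS_L:' header", call. = FALSE)
  sdv <- if (!is.na(p["biomass_sd"])) as.numeric(p[["biomass_sd"]]) else 0
  batch_series(df$time_h, df$conc_mM, df$replicate,
               biomass = as.numeric(p[["biomass_gVSS_L"]]), biomass_sd = sdv)
}

#' Read a spectral-count table
#'
#' Expects columns `protein_id`, `unique_peptides`, injection count columns
#' `inj_*`, and either an `mw` column or a companion protein FASTA from which
#' molecular weights are computed.
#'
#' @param path TSV path.
#' @param fasta Optional protein FASTA path supplying molecular weights.
#' @return A [spectral_count_table()].
#' @export
read_spectral_counts <- function(path, fasta = NULL) {
  df <- read_tsv_commented(path)
  inj <- grep("^inj_", names(df), value = TRUE)
  if (!all(c("protein_id", "unique_peptides") %in% names(df)) || !length(inj))
    stop("malformed spectral-count table ", path, call. = FALSE)
  mw <- if ("mw" %in% names(df)) {
    df$mw
  } else {
    if (is.null(fasta))
      stop("spectral-count table ", path,
           " has no 'mw' column; supply a protein FASTA", call. = FALSE)
    all_mw <- read_protein_mw(fasta)
    miss <- setdiff(df$protein_id, names(all_mw))
    if (length(miss))
      stop("protein id(s) absent from FASTA: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    unname(all_mw[df$protein_id])
  }
  spectral_count_table(df$protein_id, mw, df$unique_peptides,
                       as.matrix(df[inj]))
}

#' Read a contig-to-MAG assignment table
#'
#' Expects columns `contig_id`, `mag_id`, `length_bp`, `mapped_reads`.
#'
#' @param path TSV path.
#' @return Data frame for [mag_read_fraction()] /
#'   [mag_normalized_abundance()].
#' @export
read_contig_map <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("contig_id", "mag_id", "length_bp", "mapped_reads")
  if (!all(need %in% names(df)))
    stop("malformed contig map ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df
}

#' Packaged enrichment yield table
#'
#' The printed steady-state dilution rates and stoichiometric yields of the
#' two N2O-respiring enrichment regimes, including the two higher-dilution
#' literature chemostats used for the maintenance regression.
#'
#' @return Data frame with columns `regime`, `source`, `D`, `D_sd`, `y_x_ac`,
#'   `y_x_ac_sd`, `y_x_n2o`, `y_x_n2o_sd`, `y_n2o_ac`, `y_n2o_ac_sd`,
#'   `y_nh4_x`, `y_nh4_x_sd`.
#' @export
enrichment_yield_table <- function() {
  read_tsv_commented(system.file("extdata", "enrichment_yields.tsv",
                                 package = "chemobalance", mustWork = TRUE))
}

#' Packaged MAG read-mapping and metaproteome table
#'
#' Per-MAG mapped read counts, bin sizes and metaproteome spectra fractions
#' of the two enrichment metagenomes, with the quality-filtered read totals
#' in the header.
#'
#' @return List with `mags` (data frame `regime`, `mag_id`, `bin_size_mbp`,
#'   `mapped_reads`, `spectra_pct`) and `total_reads` (named numeric,
#'   per regime).
#' @export
enrichment_mag_table <- function() {
  df <- read_tsv_commented(system.file("extdata", "enrichment_mags.tsv",
                                       package = "chemobalance",
                                       mustWork = TRUE))
  p <- attr(df, "params")
  tot <- p[grep("^total_reads_", names(p))]
  total_reads <- stats::setNames(as.numeric(tot),
                                 sub("^total_reads_", "", names(tot)))
  list(mags = df, total_reads = total_reads)
}
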