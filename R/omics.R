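#' Build a spectral-count table
#'
#' @param protein_id Protein identifiers (unique).
#' @param mw Molecular weights, Da (> 0).
#' @param unique_peptides Unique-peptide counts per protein (>= 0 integers).
#' @param counts Integer matrix of spectral counts, proteins x injections.
#' @return A list of class `spectral_count_table`.
#' @export
spectral_count_table <- function(protein_id, mw, unique_peptides, counts) {
  counts <- as.matrix(counts)
  stopifnot(length(protein_id) == nrow(counts),
            length(mw) == nrow(counts),
            length(unique_peptides) == nrow(counts))
  if (anyDuplicated(protein_id))
    stop("duplicate protein ids", call. = FALSE)
  if (any(mw <= 0)) stop("molecular weights must be positive", call. = FALSE)
  if (ncol(counts) < 1L) stop("need at least one injection", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("spectral counts must be non-negative integers", call. = FALSE)
  rownames(counts) <- protein_id
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("inj_", seq_len(ncol(counts)))
  structure(list(protein_id = protein_id, mw = as.numeric(mw),
                 unique_peptides = as.integer(unique_peptides),
                 counts = counts),
            class = "spectral_count_table")
}

#' Per-injection normalized spectral-count shares
#'
#' The relative abundance proxy of each protein within an injection: its
#' spectral counts divided by its molecular weight, rescaled to the sum of
#' the normalized counts of that injection,
#' \deqn{share_{ij} = (SC_{ij}/MW_i) \; / \; \sum_k (SC_{kj}/MW_k).}
#' `denominator = "raw_total"` instead rescales by the raw spectral-count
#' total of the injection (an alternative normalization sometimes quoted;
#' shares then no longer sum to one).
#'
#' @param table A [spectral_count_table()].
#' @param denominator `"mw_normalized"` (default) or `"raw_total"`.
#' @return Numeric matrix of shares, proteins x injections. Injections with
#'   zero total counts are skipped with a warning (column set to `NA`).
#' @examples
#' tab <- spectral_count_table(c("a", "b"), mw = c(5e4, 1e5),
#'                             unique_peptides = c(3, 3),
#'                             counts = cbind(inj_1 = c(10, 10)))
#' normalize_spectral_counts(tab)  # 2/3, 1/3
#' @export
normalize_spectral_counts <- function(table,
                                      denominator = c("mw_normalized",
                                                      "raw_total")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(table, "spectral_count_table"))
  nsc <- table$counts / table$mw
  tot <- if (denominator == "mw_normalized") colSums(nsc)
         else colSums(table$counts)
  empty <- colSums(table$counts) == 0
  if (any(empty)) {
    warning("injection(s) skipped (zero total counts): ",
            paste(colnames(table$counts)[empty], collapse = ", "),
            call. = FALSE)
    tot[empty] <- NA_real_
  }
  sweep(nsc, 2, tot, "/")
}

#' Detection filtering and injection averaging of protein abundances
#'
#' A protein is retained when it was identified by at least
#' `min_unique_peptides` unique peptides and detected (count > 0) in at least
#' `min_injections` injections. Its relative abundance is the average of its
#' per-injection shares, by default over the injections in which it was
#' detected (`average = "detected"`); `average = "all"` averages over all
#' injections, counting non-detections as zero.
#'
#' @param shares Share matrix from [normalize_spectral_counts()].
#' @param table The corresponding [spectral_count_table()].
#' @param min_unique_peptides,min_injections Detection thresholds
#'   (defaults 2 and 2, of typically 4 injections).
#' @param average `"detected"` (default) or `"all"`.
#' @return Data frame with columns `protein_id`, `unique_peptides`,
#'   `detected_in`, `mean_relative_abundance`, `retained`.
#' @export
filter_and_average <- function(shares, table, min_unique_peptides = 2,
                               min_injections = 2,
                               average = c("detected", "all")) {
  average <- match.arg(average)
  stopifnot(inherits(table, "spectral_count_table"),
            min_unique_peptides >= 1, min_injections >= 1)
  usable <- !apply(is.na(shares), 2, any)
  detected <- table$counts[, usable, drop = FALSE] > 0
  det_n <- rowSums(detected)
  sh <- shares[, usable, drop = FALSE]
  mean_ab <- if (average == "detected") {
    num <- rowSums(sh * detected)
    ifelse(det_n > 0, num / det_n, 0)
  } else {
    rowMeans(sh)
  }
  data.frame(protein_id = table$protein_id,
             unique_peptides = table$unique_peptides,
             detected_in = det_n,
             mean_relative_abundance = mean_ab,
             retained = table$unique_peptides >= min_unique_peptides &
               det_n >= min_injections)
}

#' Metaproteome fraction per MAG
#'
#' Sums the mean relative abundances of the proteins mapping to each
#' metagenome-assembled genome, times 100. Proteins without a MAG assignment
#' are accumulated under the `unbinned` label.
#'
#' @param abundances Output of [filter_and_average()].
#' @param protein_map Data frame with columns `protein_id`, `mag_id` (use
#'   `NA` or `"unbinned"` for unbinned proteins).
#' @param retained_only Use only retained proteins (default `TRUE`).
#' @param unbinned_label Label for the unbinned row.
#' @return Data frame with columns `mag_id`, `spectra_pct`, sorted
#'   decreasingly with the unbinned row last.
#' @export
mag_proteome_fraction <- function(abundances, protein_map,
                                  retained_only = TRUE,
                                  unbinned_label = "unbinned") {
  stopifnot(all(c("protein_id", "mag_id") %in% names(protein_map)))
  ab <- if (retained_only) abundances[abundances$retained, , drop = FALSE]
        else abundances
  idx <- match(ab$protein_id, protein_map$protein_id)
  if (anyNA(idx))
    stop("assignment error: protein id(s) without MAG assignment: ",
         paste(utils::head(ab$protein_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  mag <- protein_map$mag_id[idx]
  mag[is.na(mag) | mag == ""] <- unbinned_label
  agg <- tapply(ab$mean_relative_abundance, mag, sum)
  out <- data.frame(mag_id = names(agg), spectra_pct = 100 * as.numeric(agg))
  unb <- out$mag_id == unbinned_label
  out <- rbind(out[!unb, ][order(-out$spectra_pct[!unb]), ], out[unb, ])
  rownames(out) <- NULL
  out
}

#' Fraction of quality-filtered reads mapped per MAG
#'
#' The percentage of all quality-filtered reads that map to the contigs of
#' each MAG, plus the summed binned fraction.
#'
#' @param contig_map Data frame with columns `contig_id`, `mag_id`,
#'   `length_bp` (> 0), `mapped_reads` (>= 0). Each contig maps to at most
#'   one MAG; a `mag_id` of `NA` or `"unbinned"` marks unbinned contigs. A
#'   table already aggregated per MAG (one row per MAG) is equally valid —
#'   the result is invariant to contig-level regrouping.
#' @param total_reads Total quality-filtered reads (>= sum of mapped reads).
#' @param unbinned_label Label treated as unbinned.
#' @return List with `per_mag` (data frame `mag_id`, `mapped_reads`,
#'   `read_pct`) and `binned_pct` (summed fraction over the binned MAGs).
#' @examples
#' cm <- data.frame(contig_id = "c1", mag_id = "MAG1", length_bp = 1e6,
#'                  mapped_reads = 62591220)
#' mag_read_fraction(cm, total_reads = 75.2e6)$per_mag$read_pct  # 83.2
#' @export
mag_read_fraction <- function(contig_map, total_reads,
                              unbinned_label = "unbinned") {
  stopifnot(all(c("mag_id", "mapped_reads") %in% names(contig_map)))
  if (anyDuplicated(stats::na.omit(contig_map$contig_id)))
    stop("input error: duplicated contig ids", call. = FALSE)
  if (any(contig_map$mapped_reads < 0))
    stop("input error: negative read counts", call. = FALSE)
  if (total_reads < sum(contig_map$mapped_reads))
    stop("input error: total reads smaller than the sum of mapped reads",
         call. = FALSE)
  mag <- as.character(contig_map$mag_id)
  mag[is.na(mag) | mag == ""] <- unbinned_label
  reads <- tapply(contig_map$mapped_reads, mag, sum)
  per_mag <- data.frame(mag_id = names(reads),
                        mapped_reads = as.numeric(reads),
                        read_pct = 100 * as.numeric(reads) / total_reads)
  per_mag <- per_mag[order(-per_mag$read_pct), ]
  rownames(per_mag) <- NULL
  binned <- per_mag$mag_id != unbinned_label
  list(per_mag = per_mag, binned_pct = sum(per_mag$read_pct[binned]))
}

#' Length-normalized relative abundance per MAG
#'
#' Read density of a MAG — mapped reads divided by the summed length of its
#' contigs — rescaled over all MAGs (the unbinned pool enters as a pseudo-bin
#' when present). This is the organism-abundance estimate: two equally
#' abundant populations receive equal values regardless of genome size.
#'
#' @inheritParams mag_read_fraction
#' @param include_unbinned Include the unbinned pseudo-bin in the
#'   normalization (default `TRUE` when present).
#' @return Data frame with columns `mag_id`, `length_bp`, `mapped_reads`,
#'   `density`, `rel_abundance` (sums to 1).
#' @export
mag_normalized_abundance <- function(contig_map, include_unbinned = TRUE,
                                     unbinned_label = "unbinned") {
  stopifnot(all(c("mag_id", "length_bp", "mapped_reads") %in%
                  names(contig_map)))
  mag <- as.character(contig_map$mag_id)
  mag[is.na(mag) | mag == ""] <- unbinned_label
  if (!include_unbinned) {
    keep <- mag != unbinned_label
    contig_map <- contig_map[keep, , drop = FALSE]
    mag <- mag[keep]
  }
  len <- tapply(contig_map$length_bp, mag, sum)
  if (any(len <= 0))
    stop("input error: MAG with non-positive total contig length: ",
         paste(names(len)[len <= 0], collapse = ", "), call. = FALSE)
  reads <- tapply(contig_map$mapped_reads, mag, sum)
  dens <- as.numeric(reads) / as.numeric(len)
  out <- data.frame(mag_id = names(len), length_bp = as.numeric(len),
                    mapped_reads = as.numeric(reads), density = dens,
                    rel_abundance = dens / sum(dens))
  out <- out[order(-out$rel_abundance), ]
  rownames(out) <- NULL
  out
}

# Expasy average residue masses (monomer minus water), Da
.residue_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.water_mass <- 18.01524

#' Average protein molecular weight from sequence
#'
#' Sum of average amino-acid residue masses plus one water, Da. Sequences
#' containing non-standard residues (B, J, O, U, X, Z, gaps) raise an error.
#'
#' @param seq Character vector of one-letter amino-acid sequences.
#' @return Numeric vector of molecular weights, Da.
#' @examples
#' protein_mw("PEPTIDE")  # ~799.8 Da
#' @export
protein_mw <- function(seq) {
  vapply(toupper(seq), function(s) {
    aa <- strsplit(gsub("\\*$", "", s), "")[[1]]
    bad <- setdiff(aa, names(.residue_mass))
    if (length(bad))
      stop("non-standard residue(s) in sequence: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    sum(.residue_mass[aa]) + .water_mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Molecular weights from a protein FASTA file
#'
#' @param path Path to a protein FASTA file (wrapped or unwrapped).
#' @return Named numeric vector of average molecular weights, Da; names are
#'   the first whitespace-delimited token of each FASTA header.
#' @export
read_protein_mw <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  mw <- protein_mw(as.character(aa))
  names(mw) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  mw
}
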