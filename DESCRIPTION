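Package: chemobalance
Title: Black-Box Stoichiometry, Rate Reconciliation and Omics Quantification
    for Chemostat Enrichment Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Elemental and electron (degree-of-reduction) balancing of
    microbial conversions, weighted least-squares reconciliation of measured
    chemostat conversion rates under conservation constraints with a
    chi-squared gross-error test, stoichiometric yields with linear error
    propagation, Herbert-Pirt maintenance estimation across dilution rates,
    batch specific-rate regression, and the relative-abundance arithmetic for
    metagenome-assembled genomes (read fractions, length-normalized
    abundances) and metaproteomes (molecular-weight-normalized spectral
    counts with detection filters). Includes ground-truth synthetic-data
    generators emulating steady-state chemostat measurements, linear batch
    depletion series, multinomial spectral-count sampling and per-contig read
    counts, so that every stage can be tested closed-loop. Developed around
    nitrous oxide-respiring enrichment cultures grown on acetate, but the
    balancing machinery is generic for C/H/O/N/charge systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
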