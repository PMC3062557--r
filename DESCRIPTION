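Package: cassette
Title: Cassette-Level Variation in Clonal Symbiont Genomes and Cyanobactin Mass Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of near-identical bacterial symbiont genomes
    whose dominant variable feature is the presence or absence of secondary
    metabolite gene cluster cassettes. Provides a synthetic clonal-population
    generator with full ground truth, anchor-based synteny and average
    nucleotide identity estimation, integration-locus occupancy calling with a
    three-level variation classification (cluster presence/absence, internal
    functional crossovers, hypervariable core cassettes), in-silico PCR
    genotyping with a dual presence/absence assay control, a permutation test
    for pathway co-occurrence, and prediction of cyanobactin (ribosomal
    macrocyclic peptide) molecular formulas, protonated monoisotopic masses and
    isoprene neutral-loss fragment ladders from precursor core sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
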