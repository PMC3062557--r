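# Independent oracles used across the suite. These deliberately take a
# different route from the package implementation: masses are summed one
# atom at a time from an independently typed mass table, peptide formulas
# are derived from free amino-acid molecular formulas (not residue
# formulas), and sequence identity comes from full quadratic global
# alignment rather than seed-chain-extend.

# CODATA/IUPAC monoisotopic masses, typed independently of the package's
# constant table.
.oracle_masses <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                    O = 15.9949146221, S = 31.97207069)
.oracle_proton <- 1.00727646688

# Parse a Hill formula string and sum per-atom masses one atom at a time.
oracle_mz <- function(formula_str, charge = 1L) {
  parts <- regmatches(formula_str,
                      gregexpr("([A-Z])([0-9]*)", formula_str))[[1]]
  total <- 0
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- sub("^[A-Z]", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    for (i in seq_len(n)) total <- total + .oracle_masses[[el]]
  }
  total + charge * .oracle_proton
}

# Free amino-acid molecular formulas (independent of the residue table).
.oracle_aa <- list(
  G = "C2H5NO2",  A = "C3H7NO2",  S = "C3H7NO3",  P = "C5H9NO2",
  V = "C5H11NO2", T = "C4H9NO3",  C = "C3H7NO2S", L = "C6H13NO2",
  I = "C6H13NO2", N = "C4H8N2O3", D = "C4H7NO4",  Q = "C5H10N2O3",
  K = "C6H14N2O2", E = "C5H9NO4", M = "C5H11NO2S", H = "C6H9N3O2",
  F = "C9H11NO2", R = "C6H14N4O2", Y = "C9H11NO3", W = "C11H12N2O2")

.oracle_parse <- function(s) {
  parts <- regmatches(s, gregexpr("([A-Z])([0-9]*)", s))[[1]]
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- sub("^[A-Z]", "", p)
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  counts
}

# Peptide formula from free amino acids: a linear n-peptide loses (n-1)
# waters to condensation; a head-to-tail macrocycle loses n.
oracle_peptide_counts <- function(seq, cyclic) {
  aas <- strsplit(seq, "")[[1]]
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  for (aa in aas) counts <- counts + .oracle_parse(.oracle_aa[[aa]])
  n_water <- if (cyclic) length(aas) else length(aas) - 1L
  counts - n_water * c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L)
}

oracle_counts_string <- function(counts) {
  keep <- counts[counts > 0]
  paste0(names(keep), ifelse(keep == 1L, "", keep), collapse = "")
}

# Full quadratic global-alignment identity (matches / alignment columns).
oracle_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global")
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# Printed high-resolution MS values (observed m/z, predicted m/z, formula,
# Delta ppm) for the three isolated/standard compounds and their
# isoprene-loss fragments, transcribed from the source report.
printed_ms <- list(
  mollamideD = list(core = "TTVTAC", n_prenyl = 3,
                    obs = 763.44345, pred = 763.44223,
                    formula = "C38H62N6O8S", ppm = 1.6),
  mollamideE = list(core = "TLSPFC", n_prenyl = 1,
                    obs = 699.35469, pred = 699.35342,
                    formula = "C35H50N6O7S", ppm = 1.8),
  trunkamide = list(core = "TSIAPFC", n_prenyl = 2,
                    obs = 838.45245, pred = 838.45312,
                    formula = "C43H63N7O8S", ppm = -0.8),
  # Several printed fragment Deltas do not recompute from the printed
  # (obs, pred) pairs themselves (a transposed pair, a dropped digit and a
  # sign flip); the assertable quantity is therefore the Delta recomputed
  # from the printed masses, kept alongside the printed figure.
  fragments = data.frame(
    parent = c("mollamideD", "mollamideD", "mollamideD",
               "mollamideE", "trunkamide", "trunkamide"),
    n_lost = c(1, 2, 3, 1, 1, 2),
    obs = c(695.37764, 627.31593, 559.25347, 631.29075, 770.39055, 702.32788),
    pred = c(695.37963, 627.31703, 559.25443, 631.29082, 770.39053, 702.32793),
    ppm_printed = c(-2.8, -1.7, -1.8, -0.01, -0.03, -0.07))
)

isoprene_neutral_mass_printed <- 68.0626

# Small-population config used by several tests (cheap but full-featured).
small_test_config <- function(seed, n_genomes = 3, occupancy = 0.5,
                              backbone_length = 30000, ...) {
  lib <- list(
    cluster_template("nrps", "nrps", 6000),
    cluster_template("ribo", "ribosomal", 6000,
                     precursor = list(leader_len = 60, n_slots = 2,
                                      core_len = 24, motif_len = 18)),
    cluster_template("cyano", "cyanobactin", 11000,
                     precursor = list(leader_len = 60, n_slots = 2,
                                      core_len = 18, motif_len = 18),
                     crossover = list(rel_start = 0.30, rel_end = 0.71,
                                      identity = 0.50))
  )
  population_config(n_genomes = n_genomes,
                    backbone_length = backbone_length,
                    cluster_library = lib, occupancy = occupancy,
                    seed = seed, ...)
}
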