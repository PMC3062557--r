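# Synthetic clonal-population generator.
#
# Emits a set of near-identical symbiont genomes that share a clonal backbone
# (>97% pairwise identity) and differ almost exclusively at integration loci
# where secondary-metabolite gene clusters are either present or cleanly
# absent. Shared clusters are >99% identical; one cluster pair carries a
# diverged central "crossover" region with per-genome breakpoint scars; short
# hypervariable core cassettes sit inside otherwise identical precursor
# genes. Full ground truth (coordinates, occupancy, cassettes, breakpoints,
# contig maps, mate links) is recorded so downstream callers can be scored
# exactly. All emitted coordinates are 0-based half-open.

.DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
}

# Codon table for reverse translation (one fixed codon per residue keeps
# cassette DNA deterministic given the peptide).
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
            E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
            M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
            Y = "TAT", V = "GTT")

#' Reverse-translate a peptide into DNA
#'
#' Uses one fixed codon per residue, so the encoding is deterministic.
#'
#' @param aa Amino-acid string.
#' @return DNA string of length `3 * nchar(aa)`.
#' @export
encode_peptide <- function(aa) {
  res <- strsplit(aa, "")[[1]]
  if (!all(res %in% names(.CODON))) stop("non-standard residue in peptide")
  paste(.CODON[res], collapse = "")
}

#' Mutate a DNA string to an exact number of matching positions
#'
#' Substitution-only: picks `nchar(dna) - n_match` positions and changes each
#' to a different base, so the Hamming identity to the input is exactly
#' `n_match / nchar(dna)`.
#'
#' @param dna Input DNA string.
#' @param n_match Number of positions to leave untouched.
#' @return Mutated DNA string.
#' @export
mutate_to_matches <- function(dna, n_match) {
  chars <- strsplit(dna, "")[[1]]
  n <- length(chars)
  stopifnot(n_match >= 0, n_match <= n)
  hit <- sample.int(n, n - n_match)
  for (i in hit) chars[i] <- sample(setdiff(.DNA_BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

# Substitution-only mutation to an approximate identity target (used for
# cluster copies and the diverged crossover segment).
.mutate_subs <- function(dna, identity, protected = integer(0)) {
  chars <- strsplit(dna, "")[[1]]
  n <- length(chars)
  elig <- setdiff(seq_len(n), protected)
  n_mut <- round((1 - identity) * n)
  n_mut <- min(n_mut, length(elig))
  if (n_mut > 0) {
    hit <- sample(elig, n_mut)
    for (i in hit) chars[i] <- sample(setdiff(.DNA_BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate the ancestral backbone sequence
#'
#' @param length Backbone length in bp (> 0).
#' @param seed Optional integer; when given, seeds the RNG (the population
#'   driver seeds once and passes `NULL`).
#' @return DNA string.
#' @export
generate_backbone <- function(length, seed = NULL) {
  if (length <= 0) stop("backbone length must be positive")
  if (!is.null(seed)) set.seed(seed)
  random_dna(length)
}

#' Derive a strain from the backbone by point mutation
#'
#' Mutation events are placed uniformly outside `protected` windows.
#' Substitutions dominate (95%); the remainder are small indels with
#' geometric lengths. The event budget is scaled so that global alignment
#' identity to the backbone lands within about 0.002 of `identity_target`.
#'
#' @param backbone DNA string (the ancestral sequence).
#' @param identity_target Target alignment identity in (0.9, 1].
#' @param protected Optional data frame of 0-based half-open windows
#'   (`start`, `end`) exempt from mutation (conserved flanking genes).
#' @param sub_frac Fraction of mutation events that are substitutions.
#' @return List with `seq` (mutated DNA) and `map`, a function mapping
#'   0-based backbone insertion points to 0-based derived insertion points.
#' @export
derive_strain <- function(backbone, identity_target, protected = NULL,
                          sub_frac = 0.95) {
  stopifnot(identity_target > 0.9, identity_target <= 1)
  chars <- strsplit(backbone, "")[[1]]
  n <- length(chars)
  elig <- rep(TRUE, n)
  if (!is.null(protected) && nrow(protected)) {
    for (i in seq_len(nrow(protected))) {
      a <- max(1L, protected$start[i] + 1L)
      b <- min(n, protected$end[i])
      if (b >= a) elig[a:b] <- FALSE
    }
  }
  # indel events average ~2 bp, so each event costs ~1.05 identity points
  # per bp relative to a pure-substitution budget
  n_events <- round((1 - identity_target) * n / (sub_frac + (1 - sub_frac) * 2))
  keep <- rep(TRUE, n)
  ins_after <- integer(n + 1L) # counts of inserted bases after position i (0..n)
  ins_seq <- vector("list", n + 1L)
  if (n_events > 0) {
    pos <- sample(which(elig), min(n_events, sum(elig)))
    kind <- sample(c("sub", "ins", "del"), length(pos), replace = TRUE,
                   prob = c(sub_frac, (1 - sub_frac) / 2, (1 - sub_frac) / 2))
    for (j in seq_along(pos)) {
      p <- pos[j]
      if (kind[j] == "sub") {
        chars[p] <- sample(setdiff(.DNA_BASES, chars[p]), 1L)
      } else if (kind[j] == "ins") {
        l <- rgeom(1L, 0.5) + 1L
        ins_after[p + 1L] <- ins_after[p + 1L] + l
        ins_seq[[p + 1L]] <- c(ins_seq[[p + 1L]], random_dna(l))
      } else {
        l <- rgeom(1L, 0.5) + 1L
        hi <- p
        while (hi < n && hi - p + 1L < l && elig[hi + 1L]) hi <- hi + 1L
        keep[p:hi] <- FALSE
      }
    }
  }
  pieces <- character(0)
  out <- character(n + 1L)
  out[1L] <- if (ins_after[1L] > 0) paste(ins_seq[[1L]], collapse = "") else ""
  for (i in seq_len(n)) {
    base <- if (keep[i]) chars[i] else ""
    ins <- if (ins_after[i + 1L] > 0) paste(ins_seq[[i + 1L]], collapse = "") else ""
    out[i + 1L] <- paste0(base, ins)
  }
  seq <- paste(out, collapse = "")
  keep_cum <- cumsum(keep)
  ins_cum <- cumsum(ins_after)
  map <- function(x0) {
    # x0: 0-based insertion point on the backbone (0..n)
    vapply(x0, function(x) {
      stopifnot(x >= 0, x <= n)
      kc <- if (x == 0) 0L else keep_cum[x]
      kc + ins_cum[x + 1L]
    }, numeric(1))
  }
  list(seq = seq, map = map)
}

#' Describe a gene cluster template
#'
#' @param id Cluster/pathway identifier.
#' @param kind One of `"nrps"`, `"pks"`, `"terpene"`, `"ribosomal"`,
#'   `"cyanobactin"`.
#' @param length Cluster length in bp.
#' @param precursor `NULL`, or a list describing an embedded precursor gene:
#'   `leader_len`, `n_slots`, `core_len` (bp per cassette, multiple of 3,
#'   at most 30), `motif_len` (conserved recognition flanks around each
#'   cassette).
#' @param crossover `NULL`, or a list describing a central swappable region:
#'   `rel_start`, `rel_end` (fractions of cluster length), `identity`
#'   (divergence target of the alternative central region, in the 0.25-0.77
#'   band).
#' @return A `cluster_template` stub (sequence is drawn by
#'   [simulate_population()]).
#' @export
cluster_template <- function(id, kind, length, precursor = NULL,
                             crossover = NULL) {
  stopifnot(kind %in% c("nrps", "pks", "terpene", "ribosomal", "cyanobactin"))
  if (!is.null(precursor)) {
    stopifnot(precursor$core_len <= 30, precursor$core_len %% 3 == 0)
  }
  structure(list(id = id, kind = kind, length = as.integer(length),
                 precursor = precursor, crossover = crossover),
            class = "cluster_template")
}

#' Default cluster library
#'
#' Five pathway templates mirroring the pathway families screened in the
#' source system: a nonribosomal peptide cluster, a polyketide cluster, a
#' terpene cluster, a ribosomal peptide cluster with two hypervariable
#' cassettes, and an ~11 kbp cyanobactin cluster whose central ~4.5 kbp
#' region can be swapped for a diverged functional variant.
#'
#' @return List of [cluster_template()] objects.
#' @export
default_cluster_library <- function() {
  list(
    cluster_template("nrps", "nrps", 8000),
    cluster_template("pks", "pks", 7000),
    cluster_template("terpene", "terpene", 6000),
    cluster_template("ribo", "ribosomal", 6000,
                     precursor = list(leader_len = 60, n_slots = 2,
                                      core_len = 24, motif_len = 18)),
    cluster_template("cyano", "cyanobactin", 11000,
                     precursor = list(leader_len = 60, n_slots = 2,
                                      core_len = 18, motif_len = 18),
                     crossover = list(rel_start = 0.30, rel_end = 0.71,
                                      identity = 0.50))
  )
}

#' Configuration for the synthetic population
#'
#' Defaults encode the stated world of the analysis: a clonal backbone at
#' 97% pairwise identity, clusters >99% identical when shared, inserted or
#' absent at identical loci; a cyanobactin cluster pair whose ~4.5 kbp
#' central region diverges to ~50% identity with per-genome breakpoint scars
#' offset by 5 bp (5') and ~300 bp (3'); hypervariable <=30 bp cassettes
#' inside otherwise identical precursor genes.
#'
#' @param n_genomes Number of genomes.
#' @param backbone_length Backbone length (bp). The source chromosomes are
#'   ~6 Mbp; the default is desk scale.
#' @param divergence Per-genome divergence from the ancestor. Default
#'   `0.015` for every genome gives ~97% pairwise identity (the first genome
#'   can be given higher divergence to mirror a more distant reference).
#' @param flank_len Conserved flank length (bp) on each side of every locus;
#'   these windows are exempt from backbone mutation (conserved flanking
#'   genes).
#' @param cluster_library List of [cluster_template()].
#' @param occupancy Either a probability (clusters present independently with
#'   this probability per genome) or a character matrix
#'   (genomes x clusters) with entries `"present"`, `"absent"` or
#'   `"residual"` (a short remnant fragment of the cluster).
#' @param cluster_identity Identity of shared cluster copies to the template
#'   (> 0.99).
#' @param crossover_variant_genomes Indices of genomes whose cyanobactin
#'   copy carries the diverged central region.
#' @param crossover_offsets_5,crossover_offsets_3 Per-variant-genome
#'   breakpoint offsets (bp) applied to the 5' and 3' crossover junctions.
#' @param cassette_cores Optional named list: cluster id -> matrix of
#'   amino-acid cores (genomes x slots). Default: random peptides per
#'   genome/slot.
#' @param repeat_flank_prob Probability that a locus is flanked by copies of
#'   a multi-copy repeat element (replacing its unique flank anchors).
#' @param repeat_len Repeat element length (bp).
#' @param contig_N50 Target contig N50 (bp) for [fragment_with_mates()].
#' @param mate_insert_mean,mate_insert_sd,mate_n Mate-pair insert
#'   distribution and count per genome.
#' @param seed Integer RNG seed; one stream drives the whole run.
#' @return A `population_config` list with defaults filled in.
#' @export
population_config <- function(n_genomes = 3,
                              backbone_length = 50000,
                              divergence = NULL,
                              flank_len = 300,
                              cluster_library = default_cluster_library(),
                              occupancy = 0.5,
                              cluster_identity = 0.997,
                              crossover_variant_genomes = c(2, 3),
                              crossover_offsets_5 = c(0, 5),
                              crossover_offsets_3 = c(0, 300),
                              cassette_cores = NULL,
                              repeat_flank_prob = 0,
                              repeat_len = 500,
                              contig_N50 = 8000,
                              mate_insert_mean = 3000,
                              mate_insert_sd = 300,
                              mate_n = 300,
                              seed = 1) {
  if (is.null(divergence)) divergence <- rep(0.015, n_genomes)
  stopifnot(length(divergence) == n_genomes,
            all(divergence >= 0), all(divergence < 0.1),
            backbone_length > 0)
  total_cluster <- sum(vapply(cluster_library, `[[`, integer(1), "length"))
  if (backbone_length < (length(cluster_library) + 1) * 2 * flank_len) {
    stop("backbone too short for the locus layout")
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    backbone_length = as.integer(backbone_length),
    divergence = divergence,
    flank_len = as.integer(flank_len),
    cluster_library = cluster_library,
    occupancy = occupancy,
    cluster_identity = cluster_identity,
    crossover_variant_genomes = crossover_variant_genomes,
    crossover_offsets_5 = crossover_offsets_5,
    crossover_offsets_3 = crossover_offsets_3,
    cassette_cores = cassette_cores,
    repeat_flank_prob = repeat_flank_prob,
    repeat_len = as.integer(repeat_len),
    contig_N50 = as.integer(contig_N50),
    mate_insert_mean = mate_insert_mean,
    mate_insert_sd = mate_insert_sd,
    mate_n = as.integer(mate_n),
    seed = as.integer(seed)
  ), class = "population_config")
}

# Draw template sequences, embed precursor scaffolds and the alternative
# crossover segment. Returns templates with $seq and resolved coordinates
# (1-based internal).
.realize_templates <- function(library) {
  lapply(library, function(tpl) {
    tpl$seq <- random_dna(tpl$length)
    if (!is.null(tpl$crossover)) {
      cs <- round(tpl$crossover$rel_start * tpl$length)
      ce <- round(tpl$crossover$rel_end * tpl$length)
      tpl$crossover$start <- cs # 1-based start of central region
      tpl$crossover$end <- ce   # 1-based inclusive end
      central <- substr(tpl$seq, cs, ce)
      tpl$crossover$alt_central <- .mutate_subs(central, tpl$crossover$identity)
    }
    if (!is.null(tpl$precursor)) {
      pr <- tpl$precursor
      unit <- pr$leader_len +
        pr$n_slots * (2 * pr$motif_len + pr$core_len)
      # place the precursor gene in the 3' quarter, clear of the crossover
      pstart <- tpl$length - unit - 200
      stopifnot(pstart > 0)
      if (!is.null(tpl$crossover)) stopifnot(pstart > tpl$crossover$end)
      slots <- data.frame(slot = seq_len(pr$n_slots), pre_start = NA_integer_,
                          core_start = NA_integer_, core_end = NA_integer_,
                          post_end = NA_integer_)
      cur <- pstart + pr$leader_len
      pr$pre_motifs <- character(pr$n_slots)
      pr$post_motifs <- character(pr$n_slots)
      for (s in seq_len(pr$n_slots)) {
        slots$pre_start[s] <- cur
        slots$core_start[s] <- cur + pr$motif_len
        slots$core_end[s] <- slots$core_start[s] + pr$core_len - 1L
        slots$post_end[s] <- slots$core_end[s] + pr$motif_len
        pr$pre_motifs[s] <- substr(tpl$seq, slots$pre_start[s],
                                   slots$core_start[s] - 1L)
        pr$post_motifs[s] <- substr(tpl$seq, slots$core_end[s] + 1L,
                                    slots$post_end[s])
        cur <- slots$post_end[s] + 1L
      }
      pr$start <- pstart
      pr$end <- cur - 1L
      pr$slots <- slots
      tpl$precursor <- pr
    }
    tpl
  })
}

# Build one genome's copy of a cluster: apply crossover variant, fill
# cassette slots, then sprinkle substitutions outside protected subregions.
# Returns list(seq, cassettes = data.frame, breakpoints or NULL).
.realize_cluster_copy <- function(tpl, genome_idx, config) {
  seq <- tpl$seq
  protected <- integer(0)
  breakpoints <- NULL
  shift <- 0L
  if (!is.null(tpl$crossover) &&
      genome_idx %in% config$crossover_variant_genomes) {
    vi <- match(genome_idx, config$crossover_variant_genomes)
    off5 <- config$crossover_offsets_5[vi]
    off3 <- config$crossover_offsets_3[vi]
    b5 <- tpl$crossover$start + off5
    b3 <- tpl$crossover$end + off3
    alt <- tpl$crossover$alt_central
    seq <- paste0(substr(seq, 1, b5 - 1L), alt,
                  substr(seq, b3 + 1L, nchar(seq)))
    shift <- nchar(alt) - (b3 - b5 + 1L)
    # breakpoints in template coordinates (0-based): where flank identity ends
    breakpoints <- c(b5 - 1L, b3)
    protected <- c(protected, seq(b5, b5 + nchar(alt) - 1L))
  } else if (!is.null(tpl$crossover)) {
    breakpoints <- NULL
  }
  cassettes <- NULL
  if (!is.null(tpl$precursor)) {
    pr <- tpl$precursor
    rows <- vector("list", pr$n_slots)
    dshift <- 0L # accumulates length changes from variable-length cassettes
    for (s in seq_len(pr$n_slots)) {
      cs <- pr$slots$core_start[s] + shift + dshift
      ce <- pr$slots$core_end[s] + shift + dshift
      core_aa <- NULL
      if (!is.null(config$cassette_cores) &&
          !is.null(config$cassette_cores[[tpl$id]])) {
        core_aa <- config$cassette_cores[[tpl$id]][genome_idx, s]
      }
      if (is.null(core_aa) || is.na(core_aa)) {
        core_aa <- paste(sample(names(.CODON), pr$core_len / 3,
                                replace = TRUE), collapse = "")
      }
      core_dna <- encode_peptide(core_aa)
      if (nchar(core_dna) > 30L) stop("cassette longer than 30 bp")
      seq <- paste0(substr(seq, 1, cs - 1L), core_dna,
                    substr(seq, ce + 1L, nchar(seq)))
      dshift <- dshift + nchar(core_dna) - (ce - cs + 1L)
      rows[[s]] <- data.frame(slot = s, start = cs - 1L,
                              end = cs - 1L + nchar(core_dna),
                              dna = core_dna, aa = core_aa,
                              stringsAsFactors = FALSE)
    }
    cassettes <- do.call(rbind, rows)
    # the whole precursor gene (leader + motifs + cassettes) is conserved
    protected <- c(protected, seq(pr$start + shift, pr$end + shift + dshift))
  }
  seq <- .mutate_subs(seq, config$cluster_identity, protected = protected)
  list(seq = seq, cassettes = cassettes, breakpoints = breakpoints)
}

#' Simulate a clonal population of symbiont genomes with ground truth
#'
#' Runs the whole generator: ancestral backbone, locus layout, per-strain
#' backbone divergence, cluster insertion per the occupancy matrix,
#' crossover-variant planting, cassette filling, and optional repeat
#' flanking. A single RNG stream (seeded from `config$seed`) drives the run,
#' so output is byte-identical per seed.
#'
#' @param config A [population_config()].
#' @return A `population` list: `config`, `backbone`, `templates`, `loci`
#'   (locus table with flank anchor sequences), `genomes` (named DNA
#'   strings), and `truth` (occupancy matrix, feature coordinates, cassette
#'   table, crossover breakpoints). Coordinates in truth tables are 0-based
#'   half-open.
#' @export
simulate_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  L <- config$backbone_length
  backbone <- generate_backbone(L)
  templates <- .realize_templates(config$cluster_library)
  m <- length(templates)
  fl <- config$flank_len

  # evenly spaced insertion points, >= 2*flank_len apart and off the ends
  pos <- round(seq(from = L / (m + 1), by = L / (m + 1), length.out = m))
  loci <- data.frame(
    locus_id = sprintf("locus_%s", vapply(templates, `[[`, character(1), "id")),
    cluster_id = vapply(templates, `[[`, character(1), "id"),
    backbone_pos = as.integer(pos), # 0-based insertion point
    repeat_flanked = logical(m),
    stringsAsFactors = FALSE
  )

  # multi-copy repeat element, optionally replacing flank windows
  repeat_seq <- random_dna(config$repeat_len)
  bchars <- strsplit(backbone, "")[[1]]
  if (config$repeat_flank_prob > 0) {
    loci$repeat_flanked <- runif(m) < config$repeat_flank_prob
    for (j in which(loci$repeat_flanked)) {
      p <- loci$backbone_pos[j]
      left <- .mutate_subs(repeat_seq, 0.99)
      right <- .mutate_subs(repeat_seq, 0.99)
      rl <- config$repeat_len
      stopifnot(p - rl >= 1, p + rl <= L)
      bchars[(p - rl + 1):p] <- strsplit(left, "")[[1]]
      bchars[(p + 1):(p + rl)] <- strsplit(right, "")[[1]]
    }
    if (any(loci$repeat_flanked)) {
      # plant two extra decoy copies well away from any locus
      for (dp in round(c(0.02, 0.98) * (L - config$repeat_len))) {
        bchars[(dp + 1):(dp + config$repeat_len)] <-
          strsplit(.mutate_subs(repeat_seq, 0.99), "")[[1]]
      }
    }
    backbone <- paste(bchars, collapse = "")
  }

  loci$left_flank <- vapply(seq_len(m), function(j) {
    substr(backbone, loci$backbone_pos[j] - fl + 1L, loci$backbone_pos[j])
  }, character(1))
  loci$right_flank <- vapply(seq_len(m), function(j) {
    substr(backbone, loci$backbone_pos[j] + 1L, loci$backbone_pos[j] + fl)
  }, character(1))

  # occupancy matrix
  occ <- config$occupancy
  if (is.numeric(occ) && length(occ) == 1L) {
    occ <- matrix(ifelse(runif(config$n_genomes * m) < occ,
                         "present", "absent"),
                  nrow = config$n_genomes, ncol = m)
  }
  stopifnot(is.matrix(occ), nrow(occ) == config$n_genomes, ncol(occ) == m,
            all(occ %in% c("present", "absent", "residual")))
  rownames(occ) <- paste0("g", seq_len(config$n_genomes))
  colnames(occ) <- loci$cluster_id

  protected <- data.frame(start = loci$backbone_pos - fl,
                          end = loci$backbone_pos + fl)

  genomes <- list()
  feat_rows <- list()
  cass_rows <- list()
  bp_rows <- list()
  for (g in seq_len(config$n_genomes)) {
    st <- derive_strain(backbone, 1 - config$divergence[g],
                        protected = protected)
    gseq <- st$seq
    dpos <- st$map(loci$backbone_pos) # 0-based derived insertion points
    ord <- order(dpos, decreasing = TRUE)
    extra <- rep(0L, m)
    for (j in ord) {
      state <- occ[g, j]
      if (state == "absent") next
      tpl <- templates[[j]]
      if (state == "present") {
        copy <- .realize_cluster_copy(tpl, g, config)
        ins <- copy$seq
      } else { # residual: a short internal remnant of the cluster
        frag_len <- min(800L, tpl$length)
        fs <- round(tpl$length * 0.4)
        ins <- substr(tpl$seq, fs, fs + frag_len - 1L)
        copy <- list(cassettes = NULL, breakpoints = NULL)
      }
      p <- dpos[j]
      gseq <- paste0(substr(gseq, 1, p), ins,
                     substr(gseq, p + 1L, nchar(gseq)))
      extra[j] <- nchar(ins)
      if (!is.null(copy$cassettes)) {
        cc <- copy$cassettes
        cc$genome <- rownames(occ)[g]
        cc$cluster_id <- tpl$id
        cass_rows[[length(cass_rows) + 1L]] <- cc
      }
      if (!is.null(copy$breakpoints)) {
        bp_rows[[length(bp_rows) + 1L]] <- data.frame(
          genome = rownames(occ)[g], cluster_id = tpl$id,
          bp5 = copy$breakpoints[1], bp3 = copy$breakpoints[2])
      }
    }
    # genome coordinates of each insert (0-based half-open), accounting for
    # upstream insertions
    shift <- c(0L, cumsum(extra)[-m])
    for (j in seq_len(m)) {
      start <- dpos[j] + shift[j]
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        genome = rownames(occ)[g], locus_id = loci$locus_id[j],
        cluster_id = loci$cluster_id[j], state = occ[g, j],
        start = start, end = start + extra[j],
        stringsAsFactors = FALSE)
    }
    genomes[[rownames(occ)[g]]] <- gseq
  }

  cassettes <- if (length(cass_rows)) do.call(rbind, cass_rows) else NULL
  # cassette coordinates above are cluster-relative (0-based); add genome
  # coordinates via the feature table
  features <- do.call(rbind, feat_rows)
  if (!is.null(cassettes)) {
    key <- paste(features$genome, features$cluster_id)
    idx <- match(paste(cassettes$genome, cassettes$cluster_id), key)
    cassettes$genome_start <- features$start[idx] + cassettes$start
    cassettes$genome_end <- features$start[idx] + cassettes$end
  }
  structure(list(
    config = config,
    backbone = backbone,
    templates = templates,
    loci = loci,
    genomes = genomes,
    truth = list(
      occupancy = occ,
      features = features,
      cassettes = cassettes,
      crossover = if (length(bp_rows)) do.call(rbind, bp_rows) else NULL
    )
  ), class = "population")
}

#' N50 of a set of lengths
#' @param lengths Integer vector of contig lengths.
#' @return The length-weighted median length.
#' @export
n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' Fragment a genome into contigs and sample mate-pair links
#'
#' Gap-free fragmentation: contig lengths are drawn uniform around a scale
#' chosen so the realized N50 lands near the target. Mate pairs are sampled
#' from the intact genome with the stated insert distribution and reported
#' in contig coordinates (0-based).
#'
#' @param genome DNA string.
#' @param N50 Target contig N50 (bp, >= 1000).
#' @param insert_mean,insert_sd Mate-pair insert length distribution.
#' @param n_mates Number of mate pairs to sample.
#' @param genome_id Label used in contig names.
#' @return List with `contigs` (data frame: `contig`, `start`, `end`, `seq`;
#'   genome coordinates 0-based half-open) and `mates` (data frame:
#'   `contig1`, `pos1`, `strand1`, `contig2`, `pos2`, `strand2`).
#'   Insert parameters are attached as attributes of `mates`.
#' @export
fragment_with_mates <- function(genome, N50, insert_mean = 3000,
                                insert_sd = 300, n_mates = 300,
                                genome_id = "g") {
  stopifnot(N50 >= 1000)
  L <- nchar(genome)
  # U(0.5c, 1.5c) lengths give a length-weighted median of ~1.118c
  cscale <- N50 / 1.118
  cuts <- 0
  while (cuts[length(cuts)] < L) {
    cuts <- c(cuts, cuts[length(cuts)] +
                round(runif(1, 0.5 * cscale, 1.5 * cscale)))
  }
  cuts[length(cuts)] <- L
  cuts <- unique(cuts)
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  contigs <- data.frame(
    contig = sprintf("%s_ctg%03d", genome_id, seq_along(starts)),
    start = starts, end = ends,
    seq = vapply(seq_along(starts),
                 function(i) substr(genome, starts[i] + 1L, ends[i]),
                 character(1)),
    stringsAsFactors = FALSE
  )
  find_ctg <- function(p) findInterval(p, starts) # p 0-based
  mates <- NULL
  if (n_mates > 0) {
    ins <- pmax(200, round(rnorm(n_mates, insert_mean, insert_sd)))
    s <- floor(runif(n_mates, 0, pmax(1, L - ins)))
    e <- s + ins - 1L # 0-based position of the last base
    i1 <- find_ctg(s); i2 <- find_ctg(e)
    mates <- data.frame(
      contig1 = contigs$contig[i1], pos1 = s - starts[i1], strand1 = "+",
      contig2 = contigs$contig[i2], pos2 = e - starts[i2], strand2 = "-",
      stringsAsFactors = FALSE
    )
    attr(mates, "insert_mean") <- insert_mean
    attr(mates, "insert_sd") <- insert_sd
  }
  list(contigs = contigs, mates = mates)
}

#' Write a simulated population to disk
#'
#' Emits one FASTA per genome, the truth feature table (GFF3-like TSV), the
#' cassette and crossover truth tables, the locus table, and a JSON manifest
#' recording the seed and file inventory.
#'
#' @param pop A `population` from [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in names(pop$genomes)) {
    f <- file.path(dir, paste0(g, ".fasta"))
    x <- Biostrings::DNAStringSet(pop$genomes[[g]])
    names(x) <- g
    Biostrings::writeXStringSet(x, f)
    files <- c(files, f)
  }
  tf <- file.path(dir, "truth_features.tsv")
  utils::write.table(pop$truth$features, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, tf)
  lf <- file.path(dir, "loci.tsv")
  utils::write.table(pop$loci, lf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, lf)
  if (!is.null(pop$truth$cassettes)) {
    cf <- file.path(dir, "truth_cassettes.tsv")
    utils::write.table(pop$truth$cassettes, cf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, cf)
  }
  manifest <- list(
    seed = pop$config$seed,
    n_genomes = pop$config$n_genomes,
    backbone_length = pop$config$backbone_length,
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
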