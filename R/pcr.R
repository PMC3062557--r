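# In-silico PCR genotyping.
#
# Each pathway gets a dual assay: a presence assay internal to the cluster
# (amplifies only when the cluster is there) and an absence assay spanning
# the empty integration junction (amplifies only when it is not, because
# an inserted cluster pushes the flanking primers too far apart). The two
# reactions are mutually exclusive by construction; a sample positive in
# both indicates a design or sample error and is raised as a hard error,
# never silently resolved.

.gc_frac <- function(s) {
  chars <- strsplit(s, "")[[1]]
  mean(chars %in% c("G", "C"))
}

# Scan a region for a primer site: fixed length, GC within bounds, and
# exactly `expect_copies` exact occurrences across the genome set.
.pick_primer <- function(region, genomes, primer_len = 20L,
                         gc_min = 0.4, gc_max = 0.6, step = 5L) {
  n <- nchar(region) - primer_len + 1L
  if (n < 1L) return(NULL)
  for (s in seq(1L, n, by = step)) {
    cand <- substr(region, s, s + primer_len - 1L)
    gc <- .gc_frac(cand)
    if (gc < gc_min || gc > gc_max) next
    copies <- vapply(genomes, function(g) {
      .count_occurrences(cand, g)
    }, numeric(1))
    if (all(copies <= 1)) {
      return(list(seq = cand, offset = s - 1L))
    }
  }
  NULL
}

.count_occurrences <- function(pattern, genome) {
  subject <- Biostrings::DNAString(genome)
  fwd <- Biostrings::countPattern(pattern, subject)
  rev <- Biostrings::countPattern(revcomp(pattern), subject)
  fwd + rev
}

#' Design a presence/absence primer assay pair for one locus
#'
#' The presence assay sits inside the cluster sequence; the absence assay
#' anchors in the two flanks so that its product is short only across an
#' empty junction. Primer sites must have 40-60% GC and occur at most once
#' in every genome of `genomes` (uniqueness control); loci whose flanks are
#' repetitive therefore come back flagged impractical.
#'
#' @param locus One row of a locus table (`locus_id`, `left_flank`,
#'   `right_flank`).
#' @param cluster_seq Reference cluster DNA.
#' @param genomes Named list of genome DNA strings used for the uniqueness
#'   check.
#' @param primer_len Primer length (nt, 18-25).
#' @param presence_product Target presence-amplicon size (bp).
#' @param max_product Longest amplifiable product (bp); an inserted cluster
#'   longer than this cannot be spanned, which is what makes the absence
#'   assay informative.
#' @return List of two `primer_assay` lists (`mode` = `presence-internal` /
#'   `absence-spanning`, `fwd`, `rev`, `min_product`, `max_product`,
#'   `impractical`, `reason`).
#' @export
design_assays <- function(locus, cluster_seq, genomes, primer_len = 20L,
                          presence_product = 500L, max_product = 5000L) {
  stopifnot(primer_len >= 18, primer_len <= 25)
  assay <- function(mode) {
    list(locus_id = locus$locus_id, mode = mode, fwd = NA_character_,
         rev = NA_character_, min_product = NA_integer_,
         max_product = max_product, impractical = TRUE,
         reason = "no valid primer site")
  }
  pres <- assay("presence-internal")
  abs_ <- assay("absence-spanning")
  if (nchar(locus$left_flank) < primer_len + 10 ||
      nchar(locus$right_flank) < primer_len + 10) {
    abs_$reason <- "flank shorter than primer"
    pres$reason <- "flank shorter than primer"
    return(list(presence = pres, absence = abs_))
  }
  # presence assay: forward primer early in the cluster, reverse primer
  # ~presence_product downstream (reverse complement of the + strand site)
  clen <- nchar(cluster_seq)
  if (clen > presence_product + 2 * primer_len) {
    f <- .pick_primer(substr(cluster_seq, 1, clen - presence_product),
                      genomes, primer_len)
    if (!is.null(f)) {
      rev_lo <- f$offset + presence_product - 100L
      rev_hi <- min(clen, f$offset + presence_product + 100L)
      r <- .pick_primer(substr(cluster_seq, rev_lo + 1L, rev_hi),
                        genomes, primer_len)
      if (!is.null(r)) {
        site_end <- rev_lo + r$offset + primer_len
        pres$fwd <- f$seq
        pres$rev <- revcomp(r$seq)
        pres$min_product <- site_end - f$offset
        pres$impractical <- FALSE
        pres$reason <- ""
      }
    }
  }
  # absence assay: forward near the 3' end of the left flank, reverse near
  # the 5' end of the right flank
  lf <- locus$left_flank
  lf_tail <- substr(lf, max(1L, nchar(lf) - 150L), nchar(lf))
  f <- .pick_primer(lf_tail, genomes, primer_len)
  r <- .pick_primer(substr(locus$right_flank, 1, 150), genomes, primer_len)
  if (!is.null(f) && !is.null(r)) {
    gap_f <- nchar(lf_tail) - (f$offset + primer_len) # bases after fwd site
    abs_$fwd <- f$seq
    abs_$rev <- revcomp(r$seq)
    abs_$min_product <- gap_f + r$offset + 2L * primer_len
    abs_$impractical <- FALSE
    abs_$reason <- ""
  } else {
    abs_$reason <- "flank primer sites repetitive or unsuitable"
  }
  list(presence = pres, absence = abs_)
}

# All match positions of a primer on one strand of the genome, allowing
# internal mismatches but none in the 3'-terminal `seed3` bases.
.primer_sites <- function(primer, subject, max_mismatch, seed3 = 3L) {
  hits <- Biostrings::matchPattern(primer, subject,
                                   max.mismatch = max_mismatch)
  if (!length(hits)) return(integer(0))
  keep <- vapply(seq_along(hits), function(i) {
    s <- as.character(hits[[i]])
    tail_a <- substr(s, nchar(s) - seed3 + 1L, nchar(s))
    tail_p <- substr(primer, nchar(primer) - seed3 + 1L, nchar(primer))
    tail_a == tail_p
  }, logical(1))
  BiocGenerics::start(hits)[keep]
}

#' Run a primer assay against a genome in silico
#'
#' Finds all convergent primer-site pairs within `max_product`, searching
#' both strands, allowing `max_mismatch` mismatches per primer but none in
#' the 3'-terminal 3 nt.
#'
#' @param genome DNA string.
#' @param assay A `primer_assay` from [design_assays()].
#' @param max_mismatch Mismatches tolerated per primer.
#' @param max_product Longest reportable product (bp).
#' @return Data frame of products: `start`, `end` (0-based half-open),
#'   `length`, `strand`. Zero rows if nothing amplifies (or the assay is
#'   flagged impractical).
#' @export
virtual_pcr <- function(genome, assay, max_mismatch = 1L,
                        max_product = 5000L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), strand = character(0))
  if (isTRUE(assay$impractical)) return(empty)
  subject <- Biostrings::DNAString(genome)
  plen_f <- nchar(assay$fwd)
  plen_r <- nchar(assay$rev)
  rows <- list()
  # forward orientation: fwd on + strand, rev primer binds - strand (its
  # reverse complement appears on the + strand downstream)
  f_pos <- .primer_sites(assay$fwd, subject, max_mismatch)
  r_pos <- .primer_sites(revcomp(assay$rev), subject, max_mismatch)
  for (fp in f_pos) {
    ok <- r_pos[r_pos + plen_r - fp <= max_product & r_pos > fp]
    for (rp in ok) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = fp - 1L, end = rp + plen_r - 1L,
        length = rp + plen_r - fp, strand = "+")
    }
  }
  # opposite orientation (assay hits the - strand of the genome)
  f_pos2 <- .primer_sites(revcomp(assay$fwd), subject, max_mismatch)
  r_pos2 <- .primer_sites(assay$rev, subject, max_mismatch)
  for (rp in r_pos2) {
    ok <- f_pos2[f_pos2 + plen_f - rp <= max_product & f_pos2 > rp]
    for (fp in ok) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = rp - 1L, end = fp + plen_f - 1L,
        length = fp + plen_f - rp, strand = "-")
    }
  }
  if (!length(rows)) return(empty)
  unique(do.call(rbind, rows))
}

#' Combine a presence and an absence reaction into a genotype call
#'
#' @param presence_result,absence_result Product tables from
#'   [virtual_pcr()] (or `NULL` for an impractical assay).
#' @return `"present"`, `"absent"` or `"unresolved"` (both reactions
#'   negative, or an assay impractical).
#' @section Control logic:
#' A positive presence reaction together with a positive absence reaction is
#' physically impossible when the assays were designed against the same
#' locus; it is raised as an error (control violation), never resolved.
#' @export
genotype_call <- function(presence_result, absence_result) {
  pres_pos <- !is.null(presence_result) && nrow(presence_result) > 0
  abs_pos <- !is.null(absence_result) && nrow(absence_result) > 0
  if (pres_pos && abs_pos) {
    stop("control violation: presence and absence reactions both positive")
  }
  if (pres_pos) return("present")
  if (abs_pos) return("absent")
  "unresolved"
}

#' Screen a set of samples for pathway presence/absence
#'
#' Designs assay pairs per locus, runs both reactions in every sample, and
#' assembles the genotype matrix. When the population's truth table is
#' supplied, recovery (agreement of resolvable cells with truth) is
#' reported.
#'
#' @param genomes Named list of genome DNA strings (samples).
#' @param loci Locus table with flank anchors.
#' @param templates List of cluster templates with `$seq` (reference copy
#'   per locus, same order as `loci`).
#' @param truth Optional truth occupancy matrix (genomes x clusters, states
#'   `present`/`absent`/`residual`).
#' @param max_product,max_mismatch See [virtual_pcr()].
#' @return List: `matrix` (character matrix samples x pathways with
#'   `present`/`absent`/`unresolved`), `assays`, `prevalence` (per-pathway
#'   fraction present among resolved), `recovery` (fraction of resolvable
#'   truth cells matched; `NA` without truth).
#' @export
build_matrix <- function(genomes, loci, templates, truth = NULL,
                         max_product = 5000L, max_mismatch = 1L) {
  m <- nrow(loci)
  assays <- vector("list", m)
  for (j in seq_len(m)) {
    assays[[j]] <- design_assays(loci[j, ], templates[[j]]$seq, genomes,
                                 max_product = max_product)
  }
  mat <- matrix("unresolved", nrow = length(genomes), ncol = m,
                dimnames = list(names(genomes), loci$cluster_id))
  for (g in seq_along(genomes)) {
    for (j in seq_len(m)) {
      pr <- virtual_pcr(genomes[[g]], assays[[j]]$presence,
                        max_mismatch = max_mismatch,
                        max_product = max_product)
      ar <- virtual_pcr(genomes[[g]], assays[[j]]$absence,
                        max_mismatch = max_mismatch,
                        max_product = max_product)
      mat[g, j] <- genotype_call(pr, ar)
    }
  }
  resolved <- mat != "unresolved"
  prevalence <- vapply(seq_len(m), function(j) {
    r <- resolved[, j]
    if (!any(r)) return(NA_real_)
    mean(mat[r, j] == "present")
  }, numeric(1))
  names(prevalence) <- loci$cluster_id
  recovery <- NA_real_
  if (!is.null(truth)) {
    comparable <- resolved & truth[rownames(mat), colnames(mat)] != "residual"
    recovery <- mean(mat[comparable] ==
                       truth[rownames(mat), colnames(mat)][comparable])
  }
  list(matrix = mat, assays = assays, prevalence = prevalence,
       recovery = recovery)
}

#' Permutation test for pathway co-occurrence
#'
#' For every pathway pair, the observed number of samples carrying both is
#' compared with a fixed-margin null obtained by independently permuting
#' each pathway's presence/absence labels across samples (column prevalences
#' are preserved exactly). The two-sided p-value is the add-one mid-p of the
#' absolute deviation from the null mean,
#' `p = (1 + #\{|T* - E| > |t - E|\} + 0.5 #\{|T* - E| = |t - E|\}) / (B + 1)`;
#' the mid-p form compensates for the strong discreteness of co-presence
#' counts, which otherwise makes the test markedly conservative.
#'
#' @param mat Character matrix (samples x pathways) with values
#'   `present`/`absent`/`unresolved`, or a logical matrix.
#' @param n_perm Number of permutations.
#' @param seed Integer seed (local RNG; the global stream is untouched).
#' @return Data frame: `pathway1`, `pathway2`, `n`, `observed_copresence`,
#'   `expected`, `p`, `note` (degenerate pairs are skipped with a note).
#' @export
cooccurrence_test <- function(mat, n_perm = 999L, seed = 1L) {
  if (is.character(mat)) {
    x <- mat == "present"
    x[mat == "unresolved"] <- NA
  } else {
    x <- mat
  }
  if (ncol(x) < 2) stop("need at least two pathways")
  cols <- colnames(x)
  if (is.null(cols)) cols <- paste0("p", seq_len(ncol(x)))
  out <- list()
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state)) assign(".Random.seed", rng_state,
                                    envir = globalenv())
  })
  set.seed(seed)
  for (j in seq_len(ncol(x) - 1L)) {
    for (k in (j + 1L):ncol(x)) {
      ok <- !is.na(x[, j]) & !is.na(x[, k])
      a <- x[ok, j]
      b <- x[ok, k]
      n <- sum(ok)
      row <- data.frame(pathway1 = cols[j], pathway2 = cols[k], n = n,
                        observed_copresence = NA_integer_,
                        expected = NA_real_, p = NA_real_, note = "",
                        stringsAsFactors = FALSE)
      if (n < 2 || length(unique(a)) < 2 || length(unique(b)) < 2) {
        row$note <- "degenerate column"
        out[[length(out) + 1L]] <- row
        next
      }
      t_obs <- sum(a & b)
      t_null <- vapply(seq_len(n_perm), function(i) {
        sum(sample(a) & sample(b))
      }, numeric(1))
      e <- mean(t_null)
      d_obs <- abs(t_obs - e)
      d_null <- abs(t_null - e)
      row$observed_copresence <- t_obs
      row$expected <- e
      row$p <- min(1, (1 + sum(d_null > d_obs) + 0.5 * sum(d_null == d_obs)) /
                     (n_perm + 1))
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
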