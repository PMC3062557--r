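# Anchor-based pairwise genome comparison: exact-match seeding, co-linear
# chaining, gapped identity, ANI, contig placement, synteny-break
# classification and mate-pair order verification.
#
# The approach is deliberately seed-chain-extend (the desk-scale stand-in
# for a whole-genome aligner): maximal exact k-mer anchors are chained
# co-linearly, inter-anchor gaps are closed by (banded) alignment, and gaps
# too large to close become reported synteny breaks.

#' Reverse complement of a DNA string
#' @param s DNA string.
#' @return The reverse complement string.
#' @export
revcomp <- function(s) {
  x <- chartr("ACGTacgt", "TGCAtgca", s)
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

.kmer_table <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(data.table::data.table(kmer = character(0),
                                            pos = integer(0)))
  data.table::data.table(kmer = substring(seq, 1:n, k:(n + k - 1L)),
                         pos = 1:n)
}

# Merge co-diagonal runs of shared k-mers into maximal exact matches.
.merge_seeds <- function(seeds, k) {
  if (!nrow(seeds)) {
    return(data.frame(ref_start = integer(0), qry_start = integer(0),
                      length = integer(0)))
  }
  seeds <- seeds[order(seeds$diag, seeds$rpos), ]
  new_run <- c(TRUE, diff(seeds$rpos) != 1L | diff(seeds$diag) != 0L)
  run <- cumsum(new_run)
  starts <- which(new_run)
  lens <- tabulate(run)
  data.frame(ref_start = seeds$rpos[starts],
             qry_start = seeds$qpos[starts],
             length = lens + k - 1L)
}

#' Find maximal exact-match anchors between two sequences
#'
#' Shared k-mers are collapsed to maximal exact matches; k-mers occurring
#' more than `max_occ` times in either sequence are masked as repeats before
#' matching.
#'
#' @param ref,qry DNA strings.
#' @param k Seed length (>= 11; default 15).
#' @param both_strands Also search the reverse complement of `qry`.
#' @param max_occ Repeat mask threshold (k-mer copy number).
#' @return Data frame with `ref_start`, `qry_start` (1-based), `length`,
#'   `strand`. Minus-strand anchors carry `qry_start` in reverse-complement
#'   coordinates (the frame chaining runs in); block reporting converts back.
#' @export
find_anchors <- function(ref, qry, k = 15L, both_strands = TRUE,
                         max_occ = 5L) {
  stopifnot(k >= 11)
  kmer <- pos <- NULL # data.table NSE
  rt <- .kmer_table(ref, k)
  rt <- rt[, if (.N <= max_occ) .SD, by = kmer]
  one_strand <- function(qseq, strand) {
    qt <- .kmer_table(qseq, k)
    qt <- qt[, if (.N <= max_occ) .SD, by = kmer]
    m <- merge(rt, qt, by = "kmer", allow.cartesian = TRUE,
               suffixes = c(".r", ".q"))
    if (!nrow(m)) {
      return(data.frame(ref_start = integer(0), qry_start = integer(0),
                        length = integer(0), strand = character(0)))
    }
    seeds <- data.frame(rpos = m$pos.r, qpos = m$pos.q,
                        diag = m$pos.r - m$pos.q)
    a <- .merge_seeds(seeds, k)
    if (nrow(a)) a$strand <- strand
    a
  }
  out <- one_strand(qry, "+")
  if (both_strands) {
    out <- rbind(out, one_strand(revcomp(qry), "-"))
  }
  out[order(out$strand, out$ref_start), , drop = FALSE]
}

# Co-linear chaining by windowed dynamic programming (score = anchored
# bases). Small anchor overlaps (up to `overlap_tol`) are tolerated because
# maximal exact matches on either side of an insertion junction can extend a
# base or two past each other by chance; the overlap is charged against the
# score. Returns a list of chains, each a data frame of anchors.
.chain_anchors <- function(anchors, max_gap = 5000L, window = 75L,
                           min_chain = 100L, overlap_tol = 25L) {
  chains <- list()
  remaining <- anchors
  while (nrow(remaining)) {
    a <- remaining[order(remaining$ref_start, remaining$qry_start), ]
    n <- nrow(a)
    rs <- a$ref_start
    qs <- a$qry_start
    len <- a$length
    score <- as.numeric(len)
    parent <- rep(NA_integer_, n)
    re <- rs + len # one past end
    qe <- qs + len
    for (i in seq_len(n)) {
      if (i == 1L) next
      for (j in max(1L, i - window):(i - 1L)) {
        rg <- rs[i] - re[j]
        qg <- qs[i] - qe[j]
        if (rg < -overlap_tol || qg < -overlap_tol ||
            rg > max_gap || qg > max_gap) next
        ov <- max(0L, -rg, -qg)
        s <- score[j] + len[i] - ov
        if (s > score[i]) {
          score[i] <- s
          parent[i] <- j
        }
      }
    }
    best <- which.max(score)
    if (score[best] < min_chain) break
    idx <- integer(0)
    cur <- best
    while (!is.na(cur)) {
      idx <- c(cur, idx)
      cur <- parent[cur]
    }
    chains[[length(chains) + 1L]] <- a[idx, , drop = FALSE]
    # drop used anchors and anything overlapping the chained ref interval
    used_lo <- rs[idx[1]]
    used_hi <- re[idx[length(idx)]]
    keep <- !(seq_len(n) %in% idx) &
      !(rs >= used_lo & (rs + len) <= used_hi)
    remaining <- a[keep, , drop = FALSE]
  }
  chains
}

.synteny_cache <- new.env(parent = emptyenv())

# Fixed DNA scoring scheme; computing it once avoids pairwiseAlignment's
# expensive per-call quality-matrix setup.
.nuc_submat <- function() {
  if (is.null(.synteny_cache$submat)) {
    .synteny_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE)
  }
  .synteny_cache$submat
}

# Global DNA alignment with the cached scoring scheme.
.align_global <- function(x, y) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), Biostrings::DNAString(y),
    type = "global", substitutionMatrix = .nuc_submat(),
    gapOpening = 4, gapExtension = 1)
}

.hamming_matches <- function(x, y) {
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  sum(cx == cy)
}

# Matches and aligned columns for one inter-anchor gap. Equal-length small
# gaps are scored by direct comparison; unequal or larger gaps by global
# alignment (the banded-extension step of seed-chain-extend).
.gap_alignment <- function(rseq, qseq) {
  rl <- nchar(rseq); ql <- nchar(qseq)
  if (rl == 0 && ql == 0) return(c(matches = 0, columns = 0))
  if (rl == 0 || ql == 0) return(c(matches = 0, columns = max(rl, ql)))
  if (rl == ql && rl <= 50) {
    return(c(matches = .hamming_matches(rseq, qseq), columns = rl))
  }
  pa <- .align_global(rseq, qseq)
  c(matches = Biostrings::nmatch(pa),
    columns = Biostrings::nchar(pa))
}

#' Chain anchors into syntenic blocks with gapped identity
#'
#' Anchors are chained co-linearly (per strand); chains are split into
#' blocks wherever either sequence jumps by more than `split_gap` bp, and
#' identity per block is computed from anchored bases plus alignment of the
#' small inter-anchor gaps.
#'
#' @param anchors Output of [find_anchors()].
#' @param ref,qry The two DNA strings the anchors refer to.
#' @param max_gap Maximum inter-anchor gap (bp) bridged within one chain.
#' @param split_gap Gap size (bp) above which a chain is split into separate
#'   blocks (the gap then becomes a reportable synteny break).
#' @return Data frame of blocks: `ref_start`, `ref_end`, `qry_start`,
#'   `qry_end` (0-based half-open, original orientations), `strand`,
#'   `identity`, `n_anchors`.
#' @export
chain_and_extend <- function(anchors, ref, qry, max_gap = 5000L,
                             split_gap = 200L) {
  empty <- data.frame(ref_start = integer(0), ref_end = integer(0),
                      qry_start = integer(0), qry_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      n_anchors = integer(0))
  if (is.null(anchors) || !nrow(anchors)) return(empty)
  qlen <- nchar(qry)
  qry_rc <- if (any(anchors$strand == "-")) revcomp(qry) else NULL
  blocks <- list()
  for (strand in unique(anchors$strand)) {
    a <- anchors[anchors$strand == strand, , drop = FALSE]
    qseq <- if (strand == "+") qry else qry_rc
    chains <- .chain_anchors(a, max_gap = max_gap)
    for (ch in chains) {
      n <- nrow(ch)
      re <- ch$ref_start + ch$length
      qe <- ch$qry_start + ch$length
      brk <- c(FALSE, (ch$ref_start[-1] - re[-n] > split_gap) |
                      (ch$qry_start[-1] - qe[-n] > split_gap))
      seg <- cumsum(brk)
      for (s in unique(seg)) {
        part <- ch[seg == s, , drop = FALSE]
        pe_r <- part$ref_start + part$length
        pe_q <- part$qry_start + part$length
        matches <- sum(part$length)
        columns <- sum(part$length)
        if (nrow(part) > 1) {
          for (i in 2:nrow(part)) {
            ov <- max(0L, pe_r[i - 1L] - part$ref_start[i],
                      pe_q[i - 1L] - part$qry_start[i])
            if (ov > 0L) { # overlapping anchors: un-count the overlap
              matches <- matches - ov
              columns <- columns - ov
              next
            }
            rg <- substr(ref, pe_r[i - 1L], part$ref_start[i] - 1L)
            qg <- substr(qseq, pe_q[i - 1L], part$qry_start[i] - 1L)
            if (pe_r[i - 1L] > part$ref_start[i] - 1L) rg <- ""
            if (pe_q[i - 1L] > part$qry_start[i] - 1L) qg <- ""
            ga <- .gap_alignment(rg, qg)
            matches <- matches + ga["matches"]
            columns <- columns + ga["columns"]
          }
        }
        r0 <- part$ref_start[1] - 1L
        r1 <- pe_r[nrow(part)] - 1L
        q0 <- part$qry_start[1] - 1L
        q1 <- pe_q[nrow(part)] - 1L
        if (strand == "-") {
          tmp0 <- qlen - q1
          q1 <- qlen - q0
          q0 <- tmp0
        }
        blocks[[length(blocks) + 1L]] <- data.frame(
          ref_start = r0, ref_end = r1,
          qry_start = q0, qry_end = q1,
          strand = strand,
          identity = as.numeric(matches / columns),
          n_anchors = nrow(part))
      }
    }
  }
  if (!length(blocks)) return(empty)
  out <- do.call(rbind, blocks)
  out[order(out$ref_start), , drop = FALSE]
}

#' Length-weighted average nucleotide identity over syntenic blocks
#'
#' @param blocks Block table from [chain_and_extend()].
#' @param ref_len Reference sequence length (for the coverage denominator).
#' @return List with `ani` (length-weighted mean identity) and `coverage`
#'   (fraction of the reference covered by blocks).
#' @export
average_identity <- function(blocks, ref_len) {
  if (is.null(blocks) || !nrow(blocks)) stop("no syntenic blocks")
  w <- blocks$ref_end - blocks$ref_start
  list(ani = sum(blocks$identity * w) / sum(w),
       coverage = sum(w) / ref_len)
}

#' Classify inter-block synteny gaps
#'
#' Encodes the manual comparison logic used on genome-browser views of
#' near-identical genomes: a large gap on one genome with (almost) none on
#' the other is an insertion/deletion candidate at a cluster integration
#' locus; large gaps on both, or out-of-order blocks, indicate rearrangement
#' or misassembly; gaps abutting a contig terminus are uninformative.
#'
#' @param blocks Block table (one strand, sorted by `ref_start`).
#' @param cassette_min Minimum one-sided gap (bp) for a cassette candidate.
#' @param junction_max Maximum opposite-side gap (bp) for a cassette
#'   candidate.
#' @param contig_ends Optional integer vector of 0-based positions that are
#'   contig boundaries on the query; gaps within `junction_max` of one are
#'   classified `contig-end`.
#' @return Data frame of gaps with `ref_gap`, `qry_gap` and `class`.
#' @export
classify_breaks <- function(blocks, cassette_min = 2000L,
                            junction_max = 200L, contig_ends = NULL) {
  blocks <- blocks[order(blocks$ref_start), , drop = FALSE]
  n <- nrow(blocks)
  if (n < 2) {
    return(data.frame(ref_pos = integer(0), ref_gap = integer(0),
                      qry_gap = integer(0), class = character(0)))
  }
  rows <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    ref_gap <- blocks$ref_start[i + 1L] - blocks$ref_end[i]
    qry_gap <- blocks$qry_start[i + 1L] - blocks$qry_end[i]
    inversion <- blocks$strand[i] != blocks$strand[i + 1L] || qry_gap < -junction_max
    near_end <- !is.null(contig_ends) &&
      any(abs(contig_ends - blocks$qry_end[i]) <= junction_max |
          abs(contig_ends - blocks$qry_start[i + 1L]) <= junction_max)
    cls <- if (near_end) {
      "contig-end"
    } else if (inversion) {
      "rearrangement-or-misassembly"
    } else if ((ref_gap >= cassette_min && qry_gap <= junction_max) ||
               (qry_gap >= cassette_min && ref_gap <= junction_max)) {
      "cassette-candidate"
    } else if (ref_gap >= cassette_min && qry_gap >= cassette_min) {
      "rearrangement-or-misassembly"
    } else {
      "minor-gap"
    }
    rows[[i]] <- data.frame(ref_pos = blocks$ref_end[i],
                            ref_gap = ref_gap, qry_gap = qry_gap,
                            class = cls, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare two genomes end to end
#'
#' Convenience wrapper: anchors, blocks, ANI/coverage and classified breaks.
#'
#' @param ref,qry DNA strings.
#' @param k,max_gap,split_gap See [find_anchors()] and [chain_and_extend()].
#' @return List with `blocks`, `ani`, `coverage`, `breaks`.
#' @export
compare_genomes <- function(ref, qry, k = 15L, max_gap = 5000L,
                            split_gap = 200L) {
  anchors <- find_anchors(ref, qry, k = k)
  blocks <- chain_and_extend(anchors, ref, qry, max_gap = max_gap,
                             split_gap = split_gap)
  ai <- average_identity(blocks, nchar(ref))
  list(blocks = blocks, ani = ai$ani, coverage = ai$coverage,
       breaks = classify_breaks(blocks))
}

#' Map contigs onto a reference genome
#'
#' Each contig is placed by its best co-linear anchor chain (either strand).
#' Contigs whose best and second-best placements from different reference
#' regions are nearly tied are flagged ambiguous (repeats); contigs with
#' insufficient anchored coverage are unplaced.
#'
#' @param ref Reference DNA string.
#' @param contigs Data frame with `contig` and `seq` columns (e.g. from
#'   [fragment_with_mates()]).
#' @param min_len Minimum contig length considered (bp).
#' @param min_cov Minimum anchored+aligned fraction of the contig for a
#'   placement.
#' @param ambiguity_ratio Second-best/best aligned-length ratio above which
#'   a contig is called ambiguous.
#' @return Data frame: `contig`, `status` (`placed`, `ambiguous`,
#'   `unplaced`, `short`), `ref_start`, `ref_end` (0-based), `strand`,
#'   `identity`, `cov`.
#' @export
map_contigs <- function(ref, contigs, min_len = 1000L, min_cov = 0.5,
                        ambiguity_ratio = 0.95) {
  rows <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    cseq <- contigs$seq[i]
    clen <- nchar(cseq)
    row <- data.frame(contig = contigs$contig[i], status = "unplaced",
                      ref_start = NA_integer_, ref_end = NA_integer_,
                      strand = NA_character_, identity = NA_real_,
                      cov = NA_real_, stringsAsFactors = FALSE)
    if (clen < min_len) {
      row$status <- "short"
      rows[[i]] <- row
      next
    }
    anchors <- find_anchors(ref, cseq)
    blocks <- chain_and_extend(anchors, ref, cseq)
    if (nrow(blocks)) {
      blocks$aligned <- blocks$qry_end - blocks$qry_start
      blocks <- blocks[order(-blocks$aligned), , drop = FALSE]
      best <- blocks[1, ]
      cov <- best$aligned / clen
      if (cov >= min_cov) {
        distinct <- blocks[-1, , drop = FALSE]
        distinct <- distinct[distinct$ref_start > best$ref_end + 1000 |
                             distinct$ref_end < best$ref_start - 1000, ,
                             drop = FALSE]
        amb <- nrow(distinct) > 0 &&
          distinct$aligned[1] / best$aligned >= ambiguity_ratio
        row$status <- if (amb) "ambiguous" else "placed"
        row$ref_start <- best$ref_start - best$qry_start
        row$ref_end <- row$ref_start + clen
        row$strand <- best$strand
        row$identity <- best$identity
        row$cov <- cov
        if (best$strand == "-") {
          # offset so that contig position 0 maps to ref_end
          row$ref_start <- best$ref_start - (clen - best$qry_end)
          row$ref_end <- row$ref_start + clen
        }
      }
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Verify contig order and orientation with mate-pair links
#'
#' Maps each mate end through its contig placement and classifies each link
#' as concordant (consistent orientation, implied span within
#' `insert_mean +/- 3 * insert_sd`) or discordant.
#'
#' @param placements Output of [map_contigs()].
#' @param mates Mate table from [fragment_with_mates()] (insert parameters
#'   are read from its attributes unless given).
#' @param insert_mean,insert_sd Insert length distribution.
#' @return List with `links` (per-link table with `class`) and
#'   `concordant_fraction` (among links with both ends placed).
#' @export
verify_order_with_mates <- function(placements, mates,
                                    insert_mean = attr(mates, "insert_mean"),
                                    insert_sd = attr(mates, "insert_sd")) {
  if (is.null(mates) || !nrow(mates)) {
    return(list(links = data.frame(), concordant_fraction = NA_real_))
  }
  pl <- placements[placements$status == "placed", , drop = FALSE]
  idx1 <- match(mates$contig1, pl$contig)
  idx2 <- match(mates$contig2, pl$contig)
  map_end <- function(idx, pos, strand) {
    ref_pos <- ifelse(pl$strand[idx] == "+",
                      pl$ref_start[idx] + pos,
                      pl$ref_end[idx] - 1L - pos)
    ori <- ifelse(pl$strand[idx] == "+", strand,
                  ifelse(strand == "+", "-", "+"))
    list(pos = ref_pos, ori = ori)
  }
  e1 <- map_end(idx1, mates$pos1, mates$strand1)
  e2 <- map_end(idx2, mates$pos2, mates$strand2)
  both <- !is.na(idx1) & !is.na(idx2)
  span <- abs(e2$pos - e1$pos) + 1L
  ok_ori <- (e1$pos <= e2$pos & e1$ori == "+" & e2$ori == "-") |
            (e1$pos > e2$pos & e1$ori == "-" & e2$ori == "+")
  ok_span <- abs(span - insert_mean) <= 3 * insert_sd
  class <- ifelse(!both, "unplaced-end",
                  ifelse(ok_ori & ok_span, "concordant", "discordant"))
  links <- cbind(mates, data.frame(span = ifelse(both, span, NA),
                                   class = class))
  list(links = links,
       concordant_fraction = mean(class[both] == "concordant"))
}

#' Classify contigs by tetranucleotide composition
#'
#' Nearest-centroid classification on tetranucleotide frequency profiles
#' (cosine similarity) — a simple compositional stand-in for interpolated
#' Markov model classifiers used to separate symbiont contigs from
#' contaminants.
#'
#' @param contigs Data frame with `contig` and `seq`.
#' @param reference_seqs Named list of DNA strings, one per source class
#'   (centroids are their tetranucleotide profiles).
#' @param min_len Contigs shorter than this are flagged low confidence.
#' @param min_margin Minimum cosine-similarity margin between best and
#'   second-best centroid for a confident call.
#' @return Data frame: `contig`, `label`, `similarity`, `margin`,
#'   `low_confidence`.
#' @export
classify_contigs_by_composition <- function(contigs, reference_seqs,
                                            min_len = 1000L,
                                            min_margin = 0.005) {
  tetra <- function(s) {
    f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), 4L)
    f / sum(f)
  }
  centroids <- lapply(reference_seqs, tetra)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  rows <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    p <- tetra(contigs$seq[i])
    sims <- vapply(centroids, cosine, numeric(1), a = p)
    ord <- order(sims, decreasing = TRUE)
    margin <- if (length(sims) > 1) sims[ord[1]] - sims[ord[2]] else Inf
    rows[[i]] <- data.frame(
      contig = contigs$contig[i],
      label = names(sims)[ord[1]],
      similarity = sims[ord[1]],
      margin = margin,
      low_confidence = nchar(contigs$seq[i]) < min_len | margin < min_margin,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
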