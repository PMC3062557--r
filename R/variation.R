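# Integration-locus occupancy calling and three-level variation
# classification.
#
# Loci are located through their conserved flanking anchors; the sequence
# between the flanks is compared to the reference cluster copy to call
# present / absent / unresolved. Pairwise cluster differences are then
# classified into three levels: (1) presence/absence of the whole cluster,
# (2) an internal diverged segment (functional crossover) between
# high-identity flanks, (3) hypervariable short cassettes inside an
# otherwise identical cluster.

#' Locate integration loci through their flanking anchors
#'
#' Each locus is defined by two conserved flank anchor sequences (>= 200 bp).
#' Both anchors must place uniquely (allowing up to `max_mismatch_frac`
#' mismatches); multiple placements flag the locus repeat-confounded.
#'
#' @param genome DNA string.
#' @param loci Locus table with `locus_id`, `left_flank`, `right_flank`
#'   (from [simulate_population()] or a TSV).
#' @param max_mismatch_frac Mismatch fraction tolerated per flank.
#' @return Data frame: `locus_id`, `status` (`located`,
#'   `repeat-confounded`, `unresolved`), `left_end`, `right_start`
#'   (0-based; `left_end` = position after the left flank, `right_start` =
#'   start of the right flank).
#' @export
locate_loci <- function(genome, loci, max_mismatch_frac = 0.02) {
  empty <- data.frame(locus_id = character(0), status = character(0),
                      left_end = integer(0), right_start = integer(0))
  if (!nrow(loci)) return(empty)
  subject <- Biostrings::DNAString(genome)
  rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    row <- data.frame(locus_id = loci$locus_id[i], status = "unresolved",
                      left_end = NA_integer_, right_start = NA_integer_,
                      stringsAsFactors = FALSE)
    lf <- loci$left_flank[i]
    rf <- loci$right_flank[i]
    if (nchar(lf) < 200 || nchar(rf) < 200) {
      stop("flank anchors must be at least 200 bp")
    }
    hit <- function(pat) {
      mm <- floor(max_mismatch_frac * nchar(pat))
      Biostrings::matchPattern(pat, subject, max.mismatch = mm)
    }
    lh <- hit(lf)
    rh <- hit(rf)
    if (length(lh) == 1L && length(rh) == 1L) {
      row$status <- "located"
      row$left_end <- BiocGenerics::end(lh)[1]       # 0-based half-open end
      row$right_start <- BiocGenerics::start(rh)[1] - 1L
    } else if (length(lh) > 1L || length(rh) > 1L) {
      row$status <- "repeat-confounded"
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

# Identity and coverage of `seq` against `ref_seq` via the anchor chain.
.cluster_identity <- function(ref_seq, seq) {
  anchors <- find_anchors(ref_seq, seq, both_strands = FALSE)
  if (!nrow(anchors)) return(list(identity = 0, coverage = 0))
  blocks <- chain_and_extend(anchors, ref_seq, seq, split_gap = 1000L)
  if (!nrow(blocks)) return(list(identity = 0, coverage = 0))
  w <- blocks$ref_end - blocks$ref_start
  list(identity = sum(blocks$identity * w) / sum(w),
       coverage = sum(w) / nchar(ref_seq))
}

#' Call occupancy of one integration locus
#'
#' With both flanks located: a flank-to-flank distance within the junction
#' tolerance means the locus is cleanly empty (absent); an inter-flank
#' sequence of about the reference cluster's length that aligns to it at
#' high identity means present; anything else (e.g. a residual fragment of
#' the cluster left behind by partial loss) is unresolved, with the partial
#' match reported as evidence.
#'
#' @param genome DNA string.
#' @param located One row of [locate_loci()] output.
#' @param reference_cluster DNA string of the reference cluster copy.
#' @param junction_tol Maximum inter-flank distance (bp) still called a
#'   clean empty junction. The default 50 bp tolerates small scar remnants.
#' @param min_identity,min_coverage Thresholds on the inserted sequence's
#'   match to the reference cluster for a present call. Coverage of 0.5
#'   (rather than near 1) deliberately lets a homologous pathway variant
#'   whose central region has crossed over still count as occupying the
#'   locus; identity applies to the anchored (alignable) fraction.
#' @return A one-row data frame (`locus_call`): `locus_id`, `state`,
#'   `inserted_length`, `identity`, `coverage`.
#' @export
call_occupancy <- function(genome, located, reference_cluster,
                           junction_tol = 50L, min_identity = 0.9,
                           min_coverage = 0.5) {
  out <- data.frame(locus_id = located$locus_id, state = "unresolved",
                    inserted_length = NA_integer_, identity = NA_real_,
                    coverage = NA_real_, stringsAsFactors = FALSE)
  if (located$status != "located") {
    out$state <- located$status
    return(out)
  }
  d <- located$right_start - located$left_end
  out$inserted_length <- d
  if (d <= junction_tol) {
    out$state <- "absent"
    return(out)
  }
  ins <- substr(genome, located$left_end + 1L, located$right_start)
  ci <- .cluster_identity(reference_cluster, ins)
  out$identity <- ci$identity
  out$coverage <- ci$coverage
  clen <- nchar(reference_cluster)
  if (ci$identity >= min_identity && ci$coverage >= min_coverage &&
      abs(d - clen) <= 0.2 * clen) {
    out$state <- "present"
  }
  out
}

#' Windowed identity profile and two-state segmentation of a cluster pair
#'
#' Aligns two cluster copies by anchor chaining, computes the fraction of
#' exactly matched bases in sliding windows along the first sequence, and
#' segments the profile into high-identity (flank-identical) and diverged
#' states. Segment identities are then refined by global alignment of the
#' corresponding subsequences, and state-transition positions are reported
#' as crossover breakpoints (window-resolution estimates).
#'
#' @param clusterA,clusterB DNA strings (two copies of a pathway).
#' @param window Window size (bp); also the breakpoint uncertainty.
#' @param step Step between window starts (bp).
#' @param high_min Matched-base fraction at or above which a window is in
#'   the high-identity state.
#' @param low_max Matched-base fraction below which a window is diverged.
#' @return List (`crossover_profile`): `profile` (data frame `pos`,
#'   `match_frac`, `state`), `segments` (data frame `start`, `end`, `state`,
#'   `identity`), `breakpoints` (0-based positions on `clusterA` of
#'   high->low / low->high transitions), `window`.
#' @export
crossover_profile <- function(clusterA, clusterB, window = 100L, step = 20L,
                              high_min = 0.97, low_max = 0.90) {
  la <- nchar(clusterA)
  anchors <- find_anchors(clusterA, clusterB, both_strands = FALSE)
  matched <- logical(la)
  for (i in seq_len(nrow(anchors))) {
    matched[anchors$ref_start[i]:(anchors$ref_start[i] + anchors$length[i] - 1L)] <- TRUE
  }
  starts <- seq(1L, max(1L, la - window + 1L), by = step)
  frac <- vapply(starts, function(s) {
    mean(matched[s:min(la, s + window - 1L)])
  }, numeric(1))
  state <- ifelse(frac >= high_min, "high",
                  ifelse(frac < low_max, "low", NA))
  # windows in the intermediate band inherit the previous state
  for (i in seq_along(state)) {
    if (is.na(state[i])) state[i] <- if (i > 1) state[i - 1] else "high"
  }
  runs <- rle(state)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
  segments <- data.frame(
    start = starts[starts_idx] - 1L, # 0-based
    end = pmin(la, starts[ends_idx] + window - 1L),
    state = ifelse(runs$values == "high", "flank-identical", "diverged"),
    identity = NA_real_, stringsAsFactors = FALSE)
  # trim overlaps so segments partition [0, la)
  if (nrow(segments) > 1) {
    for (i in 2:nrow(segments)) segments$end[i - 1L] <- segments$start[i]
  }
  segments$end[nrow(segments)] <- la
  # refine identity per segment by global alignment of corresponding parts
  bpos <- .interpolate_qry(anchors, segments$start, nchar(clusterB))
  bpos_end <- .interpolate_qry(anchors, segments$end, nchar(clusterB))
  for (i in seq_len(nrow(segments))) {
    aseg <- substr(clusterA, segments$start[i] + 1L, segments$end[i])
    bseg <- substr(clusterB, bpos[i] + 1L, bpos_end[i])
    if (nchar(aseg) == 0 || nchar(bseg) == 0) next
    if (nchar(aseg) > 6000) {
      # large high-identity segments: anchor-based identity is accurate
      segments$identity[i] <- .cluster_identity(aseg, bseg)$identity
    } else {
      pa <- .align_global(aseg, bseg)
      segments$identity[i] <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    }
  }
  # anchor coverage underestimates identity where mismatches cluster, so
  # the coarse segmentation can split high-identity runs: reclassify each
  # segment by its refined alignment identity and merge neighbours
  segments$state <- ifelse(!is.na(segments$identity) &
                             segments$identity >= high_min,
                           "flank-identical", "diverged")
  if (nrow(segments) > 1) {
    merged <- segments[1, , drop = FALSE]
    for (i in 2:nrow(segments)) {
      j <- nrow(merged)
      if (segments$state[i] == merged$state[j]) {
        w1 <- merged$end[j] - merged$start[j]
        w2 <- segments$end[i] - segments$start[i]
        merged$identity[j] <- (merged$identity[j] * w1 +
                                 segments$identity[i] * w2) / (w1 + w2)
        merged$end[j] <- segments$end[i]
      } else {
        merged <- rbind(merged, segments[i, , drop = FALSE])
      }
    }
    segments <- merged
  }
  # refine each high/low boundary to base resolution using the anchors:
  # exact matches are absent inside a truly diverged region, so the end of
  # the last (start of the first) anchor pins the transition to within a
  # few bases, versus the window-level blur of the coarse segmentation
  if (nrow(segments) > 1 && nrow(anchors)) {
    a_start0 <- anchors$ref_start - 1L                  # 0-based start
    a_end0 <- anchors$ref_start + anchors$length - 1L   # 0-based one-past-end
    for (i in seq_len(nrow(segments) - 1L)) {
      b <- segments$start[i + 1L]
      if (segments$state[i] == "flank-identical" &&
          segments$state[i + 1L] == "diverged") {
        cand <- a_end0[a_end0 >= b - window & a_end0 <= b + window]
        if (length(cand)) b <- max(cand)
      } else if (segments$state[i] == "diverged" &&
                 segments$state[i + 1L] == "flank-identical") {
        cand <- a_start0[a_start0 >= b - window & a_start0 <= b + window]
        if (length(cand)) b <- min(cand)
      }
      segments$end[i] <- b
      segments$start[i + 1L] <- b
    }
  }
  breakpoints <- segments$start[-1L]
  list(profile = data.frame(pos = starts - 1L, match_frac = frac,
                            state = state),
       segments = segments, breakpoints = breakpoints, window = window)
}

# Map 0-based positions on the reference to the query via the nearest
# anchor (linear interpolation between anchored diagonals).
.interpolate_qry <- function(anchors, pos, qlen) {
  if (!nrow(anchors)) return(pmin(pos, qlen))
  mid_r <- anchors$ref_start + anchors$length / 2
  vapply(pos, function(p) {
    i <- which.min(abs(mid_r - p))
    off <- anchors$qry_start[i] - anchors$ref_start[i]
    max(0L, min(qlen, p + off))
  }, numeric(1))
}

#' Extract hypervariable core cassettes from a precursor gene
#'
#' Finds the conserved recognition motifs that flank each cassette slot and
#' returns the (<= `max_core`) bp between a pre-motif and the nearest
#' post-motif, together with its translation.
#'
#' @param precursor_seq DNA string containing the precursor gene.
#' @param leader_model List with `pre_motifs` and `post_motifs` (character
#'   vectors of conserved flanking DNA motifs, one pair per slot).
#' @param max_core Maximum cassette length (bp).
#' @param max_mismatch Mismatches tolerated per motif.
#' @return Data frame: `slot`, `start`, `end` (0-based half-open within
#'   `precursor_seq`), `dna`, `aa`. Zero rows (with a warning) if no motif
#'   pair matches.
#' @export
extract_cores <- function(precursor_seq, leader_model, max_core = 30L,
                          max_mismatch = 1L) {
  subject <- Biostrings::DNAString(precursor_seq)
  rows <- list()
  n_slots <- length(leader_model$pre_motifs)
  for (s in seq_len(n_slots)) {
    pre <- Biostrings::matchPattern(leader_model$pre_motifs[s], subject,
                                    max.mismatch = max_mismatch)
    post <- Biostrings::matchPattern(leader_model$post_motifs[s], subject,
                                     max.mismatch = max_mismatch)
    if (!length(pre) || !length(post)) next
    for (i in seq_along(pre)) {
      cs <- BiocGenerics::end(pre)[i] + 1L
      ok <- which(BiocGenerics::start(post) > cs &
                  BiocGenerics::start(post) - cs <= max_core)
      if (!length(ok)) next
      ce <- BiocGenerics::start(post)[ok[1]] - 1L
      dna <- substr(precursor_seq, cs, ce)
      aa <- if (nchar(dna) %% 3 == 0 && nchar(dna) > 0) {
        as.character(Biostrings::translate(Biostrings::DNAString(dna)))
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        slot = s, start = cs - 1L, end = ce, dna = dna, aa = aa,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no cassette recognition motifs matched")
    return(data.frame(slot = integer(0), start = integer(0),
                      end = integer(0), dna = character(0),
                      aa = character(0)))
  }
  do.call(rbind, rows)
}

#' Classify a pairwise cluster difference into variation levels
#'
#' Levels (several may co-occur and are all reported):
#' level 1 — occupancy differs between the two genomes;
#' level 2 — both copies present but an internal segment of >= `min_swap`
#' bp diverges below 0.90 identity between flanking segments at >= 0.99
#' (a functional crossover);
#' level 3 — copies >= 0.99 identical except at <= 30 bp cassettes inside
#' annotated precursor slots (hypervariable cores).
#'
#' @param callA,callB Locus-call rows for the two genomes (from
#'   [call_occupancy()]).
#' @param profile Optional [crossover_profile()] of the two cluster copies
#'   (required to detect levels 2 and 3).
#' @param coresA,coresB Optional cassette tables from [extract_cores()] for
#'   the two copies.
#' @param min_swap Minimum diverged-segment span (bp) for level 2.
#' @return A `variation_call` list: `levels` (integer vector), `evidence`.
#' @export
classify_variation <- function(callA, callB, profile = NULL,
                               coresA = NULL, coresB = NULL,
                               min_swap = 500L) {
  levels <- integer(0)
  evidence <- list()
  if (callA$state %in% c("repeat-confounded", "unresolved") ||
      callB$state %in% c("repeat-confounded", "unresolved")) {
    return(structure(list(levels = NA, evidence = list(
      note = "occupancy unresolved in at least one genome")),
      class = "variation_call"))
  }
  if (callA$state != callB$state) {
    levels <- c(levels, 1L)
    evidence$occupancy <- c(callA$state, callB$state)
  }
  if (callA$state == "present" && callB$state == "present" &&
      !is.null(profile)) {
    seg <- profile$segments
    div <- seg[seg$state == "diverged" &
               (seg$end - seg$start) >= min_swap, , drop = FALSE]
    div <- div[!is.na(div$identity) & div$identity < 0.90, , drop = FALSE]
    flanks_ok <- FALSE
    if (nrow(div)) {
      hi <- seg[seg$state == "flank-identical" &
                !is.na(seg$identity) & seg$identity >= 0.99, , drop = FALSE]
      flanks_ok <- nrow(hi) >= 1
    }
    if (nrow(div) && flanks_ok) {
      levels <- c(levels, 2L)
      evidence$crossover <- div
      evidence$breakpoints <- profile$breakpoints
    }
    if (!nrow(div)) {
      # identical everywhere except, at most, short windows around <= 30 bp
      # cassettes: every large segment must be high-identity, and any
      # diverged segment must be no longer than a cassette plus the window
      # blur on both sides
      big <- seg[(seg$end - seg$start) >= min_swap, , drop = FALSE]
      hi_elsewhere <- all(big$state == "flank-identical" &
                          !is.na(big$identity) & big$identity >= 0.99)
      small_div <- seg[seg$state == "diverged", , drop = FALSE]
      small_ok <- all((small_div$end - small_div$start) <=
                        30L + 2L * profile$window)
      if (hi_elsewhere && small_ok && !is.null(coresA) && !is.null(coresB) &&
          nrow(coresA) && nrow(coresB)) {
        shared <- intersect(coresA$slot, coresB$slot)
        diff_slots <- shared[vapply(shared, function(s) {
          coresA$dna[coresA$slot == s][1] != coresB$dna[coresB$slot == s][1]
        }, logical(1))]
        if (length(diff_slots)) {
          levels <- c(levels, 3L)
          evidence$cassette_slots <- diff_slots
        }
      }
    }
  }
  structure(list(levels = if (length(levels)) sort(levels) else 0L,
                 evidence = evidence),
            class = "variation_call")
}
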