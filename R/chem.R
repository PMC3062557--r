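# Cyanobactin product prediction: candidate enumeration from a core sequence
# and pathway class, protonated monoisotopic masses, isoprene-loss fragment
# ladders, and matching of observed high-resolution peaks.

#' Build a cyanobactin product from a core sequence and modification spec
#'
#' @param core Core amino-acid sequence (the segment of the precursor peptide
#'   that becomes the mature natural product).
#' @param spec A [modification_spec()].
#' @return An object of class `cyanobactin_product` with the derived formula,
#'   neutral monoisotopic mass and singly protonated m/z.
#' @export
cyanobactin_product <- function(core, spec = modification_spec()) {
  topology <- if (spec$macrocyclic) "head_to_tail_cyclic" else "linear"
  base <- peptide_formula(core, topology)
  f <- apply_spec(base, spec, core)
  structure(list(
    core = core,
    spec = spec,
    formula = f,
    neutral_mass = monoisotopic_mz(f, charge = 0L),
    mz_MH = monoisotopic_mz(f, charge = 1L)
  ), class = "cyanobactin_product")
}

#' @export
print.cyanobactin_product <- function(x, ...) {
  het <- nrow(x$spec$heterocycles)
  cat(sprintf("<cyanobactin> core %s | %s | %d heterocycle(s), %d prenyl | [M+H]+ %.5f\n",
              x$core, formula_string(x$formula), het, x$spec$n_prenyl, x$mz_MH))
  invisible(x)
}

.n_modifications <- function(spec) {
  nrow(spec$heterocycles) + spec$n_prenyl
}

#' Enumerate candidate products for a core under a pathway class
#'
#' The two cyanobactin pathway classes treat the same core chemically
#' differently. The prenylating class (tru-type) forms an azoline only at Cys
#' and attaches 0 to (#Ser + #Thr) isoprene units at Ser/Thr hydroxyls. The
#' heterocyclizing class (pat-type) oxidizes Cys to an azole and may convert
#' any number of Ser/Thr to azolines; it does not prenylate. Candidates are
#' deduplicated by molecular formula because mass spectra cannot distinguish
#' positional isomers.
#'
#' @param core Core amino-acid sequence.
#' @param pathway_class `"tru"` (prenylating) or `"pat"` (heterocyclizing).
#' @return List of `cyanobactin_product`, unique by formula.
#' @export
enumerate_candidates <- function(core, pathway_class = c("tru", "pat")) {
  pathway_class <- match.arg(pathway_class)
  stopifnot(nzchar(core))
  aas <- strsplit(core, "")[[1]]
  cys <- which(aas == "C")
  st <- which(aas %in% c("S", "T"))
  out <- list()
  if (pathway_class == "tru") {
    het <- data.frame(pos = cys, state = rep("azoline", length(cys)))
    for (k in 0:length(st)) {
      spec <- modification_spec(macrocyclic = TRUE, heterocycles = het,
                                n_prenyl = k)
      out[[length(out) + 1L]] <- cyanobactin_product(core, spec)
    }
  } else {
    het_cys <- data.frame(pos = cys, state = rep("azole", length(cys)))
    # count of Ser/Thr azolines; positions interchangeable at formula level
    for (k in 0:length(st)) {
      het <- rbind(het_cys, data.frame(pos = st[seq_len(k)],
                                       state = rep("azoline", k)))
      spec <- modification_spec(macrocyclic = TRUE, heterocycles = het,
                                n_prenyl = 0L)
      out[[length(out) + 1L]] <- cyanobactin_product(core, spec)
    }
  }
  keys <- vapply(out, function(p) formula_string(p$formula), character(1))
  out[!duplicated(keys)]
}

#' Isoprene neutral-loss fragment ladder
#'
#' Prenylated cyanobactins fragment in MS2 by sequential clean loss of
#' isoprene (C5H8, 68.0626 Da neutral). The ladder has one step per possible
#' cumulative loss, including the intact parent.
#'
#' @param product A `cyanobactin_product`.
#' @return Data frame with columns `n_lost`, `formula` (Hill string) and
#'   `mz_MH`, ordered from parent (0 lost) to fully de-prenylated.
#' @export
isoprene_ladder <- function(product) {
  stopifnot(inherits(product, "cyanobactin_product"))
  n <- product$spec$n_prenyl
  f <- product$formula
  steps <- vector("list", n + 1L)
  for (k in 0:n) {
    if (k > 0) f <- formula_subtract(f, isoprene_formula())
    steps[[k + 1L]] <- data.frame(
      n_lost = k,
      formula = formula_string(f),
      mz_MH = monoisotopic_mz(f, charge = 1L),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, steps)
}

#' Match an observed m/z against candidate products
#'
#' @param observed_mz Observed singly protonated m/z (Da).
#' @param candidates Non-empty list of `cyanobactin_product` (e.g. from
#'   [enumerate_candidates()]).
#' @param tol_ppm Match tolerance in ppm (default 5, typical for FT-ICR MS).
#' @return List with `matched` (logical), `candidate` (best product or NULL),
#'   and `ppm` (signed error of the best candidate). Ties on |ppm| are broken
#'   by the smaller number of modifications.
#' @export
match_observed <- function(observed_mz, candidates, tol_ppm = 5) {
  stopifnot(length(candidates) > 0)
  ppm <- vapply(candidates, function(p) ppm_error(observed_mz, p$mz_MH),
                numeric(1))
  nmod <- vapply(candidates, function(p) .n_modifications(p$spec), numeric(1))
  ord <- order(abs(ppm), nmod)
  best <- ord[1L]
  list(
    matched = abs(ppm[best]) <= tol_ppm,
    candidate = if (abs(ppm[best]) <= tol_ppm) candidates[[best]] else NULL,
    ppm = ppm[best]
  )
}

#' Predict products for a table of cores and match observed peaks
#'
#' Convenience report used by the pipeline: enumerates candidates per core,
#' matches each observed peak against the pooled candidate set, and tabulates
#' formulas, predicted m/z, ppm errors and fragment ladders.
#'
#' @param cores Data frame with columns `core` and `class` (`"tru"`/`"pat"`),
#'   or a character vector of cores (then all `"tru"`).
#' @param observed Optional numeric vector of observed m/z values (named or
#'   not).
#' @param tol_ppm Match tolerance in ppm.
#' @return List with `products` (all candidates, one row each), `matches`
#'   (one row per observed peak) and `ladders` (fragment ladder rows for
#'   matched candidates).
#' @export
report_chem <- function(cores, observed = numeric(0), tol_ppm = 5) {
  if (is.character(cores)) {
    cores <- data.frame(core = cores, class = "tru", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("core", "class") %in% names(cores)))
  cand <- list()
  for (i in seq_len(nrow(cores))) {
    cs <- enumerate_candidates(cores$core[i], cores$class[i])
    cand <- c(cand, cs)
  }
  products <- do.call(rbind, lapply(cand, function(p) data.frame(
    core = p$core,
    n_heterocycles = nrow(p$spec$heterocycles),
    n_prenyl = p$spec$n_prenyl,
    formula = formula_string(p$formula),
    mz_MH = p$mz_MH,
    stringsAsFactors = FALSE
  )))
  matches <- NULL
  ladders <- NULL
  if (length(observed)) {
    ids <- if (!is.null(names(observed))) names(observed)
           else paste0("peak", seq_along(observed))
    rows <- vector("list", length(observed))
    for (i in seq_along(observed)) {
      m <- match_observed(observed[i], cand, tol_ppm = tol_ppm)
      rows[[i]] <- data.frame(
        peak = ids[i],
        observed_mz = observed[i],
        matched = m$matched,
        core = if (m$matched) m$candidate$core else NA_character_,
        formula = if (m$matched) formula_string(m$candidate$formula)
                  else NA_character_,
        predicted_mz = if (m$matched) m$candidate$mz_MH else NA_real_,
        ppm = if (m$matched) round(m$ppm, 1) else NA_real_,
        stringsAsFactors = FALSE
      )
      if (m$matched) {
        lad <- isoprene_ladder(m$candidate)
        lad$peak <- ids[i]
        ladders <- rbind(ladders, lad)
      }
    }
    matches <- do.call(rbind, rows)
  }
  list(products = products, matches = matches, ladders = ladders)
}
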