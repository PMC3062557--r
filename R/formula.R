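# Elements supported in all formula arithmetic. Cyanobactins and their
# fragments are CHNOS-only molecules, so the table is deliberately small.
.CHEM_ELEMENTS <- c("C", "H", "N", "O", "S")

# Monoisotopic element masses (Da). Fixed constants; chosen so that predicted
# [M+H]+ values reproduce published FT-ICR MS figures to <= 5e-5 Da.
.MONO_MASS <- c(
  C = 12.000000,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207069
)

# Mass of a proton (Da); charge carrier for [M+H]+.
.PROTON_MASS <- 1.00727646

#' Construct a molecular formula
#'
#' A formula is a named integer vector over the elements C, H, N, O, S.
#' All mass arithmetic in the package goes through this representation.
#'
#' @param C,H,N,O,S Non-negative integer element counts.
#' @return An object of class `chem_formula`.
#' @examples
#' chem_formula(C = 5, H = 8) # isoprene
#' @export
chem_formula <- function(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L) {
  counts <- c(C = C, H = H, N = N, O = O, S = S)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("element counts must be non-negative integers")
  }
  structure(as.integer(counts), names = .CHEM_ELEMENTS, class = "chem_formula")
}

.as_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  stopifnot(is.numeric(x), !is.null(names(x)))
  out <- chem_formula()
  bad <- setdiff(names(x), .CHEM_ELEMENTS)
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  out[names(x)] <- as.integer(x)
  structure(out, class = "chem_formula")
}

#' Parse a Hill-order formula string
#'
#' @param s Formula string such as `"C38H62N6O8S"`.
#' @return A `chem_formula`.
#' @export
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  parts <- parts[nzchar(parts)]
  if (!nzchar(s) || paste(parts, collapse = "") != s) {
    stop("cannot parse formula string: ", s)
  }
  f <- chem_formula()
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% .CHEM_ELEMENTS) stop("unsupported element: ", el)
    f[el] <- f[el] + n
  }
  f
}

#' Format a formula in Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically;
#' unit counts are printed without a digit.
#'
#' @param f A `chem_formula`.
#' @return A single string.
#' @export
formula_string <- function(f) {
  f <- .as_formula(f)
  keep <- f[f > 0]
  if (!length(keep)) return("")
  paste0(names(keep), ifelse(keep == 1L, "", keep), collapse = "")
}

#' @export
format.chem_formula <- function(x, ...) formula_string(x)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", formula_string(x), "\n", sep = "")
  invisible(x)
}

#' Element-wise formula addition
#' @param a,b `chem_formula` objects.
#' @return A `chem_formula`.
#' @export
formula_add <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  structure(as.integer(unclass(a) + unclass(b)),
            names = .CHEM_ELEMENTS, class = "chem_formula")
}

#' Element-wise formula subtraction
#'
#' Errors if any resulting count would be negative: a modification can never
#' remove atoms the molecule does not have.
#'
#' @param a,b `chem_formula` objects.
#' @return A `chem_formula`.
#' @export
formula_subtract <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  out <- unclass(a) - unclass(b)
  if (any(out < 0)) {
    stop("formula subtraction would yield negative count: ",
         formula_string(a), " - ", formula_string(b))
  }
  structure(as.integer(out), names = .CHEM_ELEMENTS, class = "chem_formula")
}

#' @export
`+.chem_formula` <- function(e1, e2) formula_add(e1, e2)

#' @export
`-.chem_formula` <- function(e1, e2) formula_subtract(e1, e2)

# Residue formulas: the 20 standard amino acids as residues (monomer minus
# water), i.e. what each contributes to a peptide chain.
.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

.WATER <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
.H2 <- c(C = 0, H = 2, N = 0, O = 0, S = 0)

#' Isoprene unit formula (C5H8)
#'
#' The neutral loss characteristic of prenylated cyanobactins in tandem MS.
#'
#' @return A `chem_formula` for C5H8.
#' @export
isoprene_formula <- function() chem_formula(C = 5L, H = 8L)

#' Residue formula of a standard amino acid
#'
#' @param aa One-letter amino acid code (one of the 20 standard residues).
#' @return A `chem_formula`: the residue composition (free amino acid minus
#'   one water).
#' @export
residue_formula <- function(aa) {
  stopifnot(is.character(aa), length(aa) == 1L)
  f <- .RESIDUE_FORMULA[[aa]]
  if (is.null(f)) stop("invalid residue: '", aa, "'")
  .as_formula(f)
}

#' Molecular formula of a peptide
#'
#' Linear peptides gain one water relative to the residue sum (free termini);
#' head-to-tail macrocycles are the bare residue sum because the final
#' condensation removes that water.
#'
#' @param seq Amino-acid string of standard one-letter codes.
#' @param topology `"linear"` or `"head_to_tail_cyclic"`.
#' @return A `chem_formula`.
#' @examples
#' formula_string(peptide_formula("TTVTAC", "head_to_tail_cyclic"))
#' @export
peptide_formula <- function(seq, topology = c("linear", "head_to_tail_cyclic")) {
  topology <- match.arg(topology)
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty peptide sequence")
  aas <- strsplit(seq, "")[[1]]
  f <- chem_formula()
  for (aa in aas) f <- formula_add(f, residue_formula(aa))
  if (topology == "linear") f <- formula_add(f, .as_formula(.WATER))
  f
}

#' Specify post-translational modifications of a cyanobactin core
#'
#' @param macrocyclic Logical; head-to-tail (N-C) macrocyclization.
#' @param heterocycles Data frame with columns `pos` (1-based residue position
#'   in the core) and `state` (`"azoline"` or `"azole"`), or `NULL`.
#'   Heterocyclization is only chemically possible at Cys, Ser or Thr.
#' @param n_prenyl Number of isoprene (C5H8) units attached; only Ser/Thr
#'   hydroxyls are prenylation substrates.
#' @param prenyl_sites Optional integer vector of prenylated residue
#'   positions. MS data alone cannot localize prenyl groups, so sites may be
#'   left `NULL` with only the count specified.
#' @return An object of class `modification_spec`.
#' @export
modification_spec <- function(macrocyclic = TRUE, heterocycles = NULL,
                              n_prenyl = 0L, prenyl_sites = NULL) {
  if (is.null(heterocycles)) {
    heterocycles <- data.frame(pos = integer(), state = character())
  }
  stopifnot(is.data.frame(heterocycles),
            all(c("pos", "state") %in% names(heterocycles)),
            all(heterocycles$state %in% c("azoline", "azole")),
            n_prenyl >= 0)
  structure(list(macrocyclic = isTRUE(macrocyclic),
                 heterocycles = heterocycles,
                 n_prenyl = as.integer(n_prenyl),
                 prenyl_sites = prenyl_sites),
            class = "modification_spec")
}

.validate_spec <- function(spec, core) {
  aas <- strsplit(core, "")[[1]]
  for (i in seq_len(nrow(spec$heterocycles))) {
    p <- spec$heterocycles$pos[i]
    if (p < 1 || p > length(aas) || !aas[p] %in% c("C", "S", "T")) {
      stop("heterocycle at position ", p,
           " is not a Cys/Ser/Thr residue of the core")
    }
  }
  n_st <- sum(aas %in% c("S", "T"))
  if (spec$n_prenyl > n_st) {
    stop("n_prenyl (", spec$n_prenyl, ") exceeds Ser+Thr count (", n_st, ")")
  }
  if (!is.null(spec$prenyl_sites)) {
    if (length(spec$prenyl_sites) != spec$n_prenyl) {
      stop("prenyl_sites length must equal n_prenyl")
    }
    if (!all(aas[spec$prenyl_sites] %in% c("S", "T"))) {
      stop("prenyl sites must be Ser or Thr residues")
    }
  }
  invisible(TRUE)
}

#' Apply a modification spec to a base peptide formula
#'
#' Each azoline heterocycle is a cyclodehydration (-H2O); an azole is the
#' further oxidized ring (an additional -H2). Each prenyl group adds one
#' isoprene unit (+C5H8).
#'
#' @param base `chem_formula` of the (cyclic or linear) peptide backbone.
#' @param spec A [modification_spec()].
#' @param core The core amino-acid sequence, used to validate that the spec is
#'   chemically possible.
#' @return A `chem_formula` for the mature product.
#' @export
apply_spec <- function(base, spec, core) {
  stopifnot(inherits(spec, "modification_spec"))
  .validate_spec(spec, core)
  f <- .as_formula(base)
  for (i in seq_len(nrow(spec$heterocycles))) {
    f <- formula_subtract(f, .as_formula(.WATER))
    if (spec$heterocycles$state[i] == "azole") {
      f <- formula_subtract(f, .as_formula(.H2))
    }
  }
  if (spec$n_prenyl > 0L) {
    for (k in seq_len(spec$n_prenyl)) f <- formula_add(f, isoprene_formula())
  }
  f
}

#' Monoisotopic mass-to-charge ratio
#'
#' @param f A `chem_formula` (neutral molecule).
#' @param charge Number of protons added (0 gives the neutral monoisotopic
#'   mass; 1 gives singly protonated `[M+H]+`).
#' @return Mass (Da) as a double; report with 5 decimals.
#' @examples
#' monoisotopic_mz(parse_formula("C38H62N6O8S"), charge = 1) # 763.44226
#' @export
monoisotopic_mz <- function(f, charge = 1L) {
  f <- .as_formula(f)
  sum(unclass(f) * .MONO_MASS[names(f)]) + charge * .PROTON_MASS
}

#' Parts-per-million mass error
#'
#' @param observed,predicted Masses in Da; `predicted` must be positive.
#' @return Signed ppm error, `(observed - predicted) / predicted * 1e6`.
#'   Report rounded to one decimal.
#' @export
ppm_error <- function(observed, predicted) {
  stopifnot(predicted > 0)
  (observed - predicted) / predicted * 1e6
}
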