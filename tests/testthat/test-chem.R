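# Chemistry: formula arithmetic, residue/peptide composition, modification
# specs, monoisotopic masses, ppm errors, candidate enumeration, fragment
# ladders and observed-mass matching.

test_that("residue formulas agree with the free amino-acid oracle", {
  for (aa in names(cassette:::.RESIDUE_FORMULA)) {
    expected <- .oracle_parse(.oracle_aa[[aa]]) -
      c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L)
    got <- residue_formula(aa)
    expect_equal(unclass(got)[names(expected)], expected, label = aa)
  }
  expect_equal(formula_string(residue_formula("G")), "C2H3NO")
  expect_equal(formula_string(residue_formula("C")), "C3H5NOS")
  expect_equal(formula_string(residue_formula("W")), "C11H10N2O")
  expect_error(residue_formula("B"), "invalid residue")
})

test_that("peptide formulas match the summation oracle for both topologies", {
  cases <- list(c("TTVTAC", "head_to_tail_cyclic"),
                c("TLSPFC", "head_to_tail_cyclic"),
                c("TSIAPFC", "head_to_tail_cyclic"),
                c("G", "linear"),
                c("ACDEFGHIKLMNPQRSTVWY", "linear"))
  for (cs in cases) {
    got <- peptide_formula(cs[1], cs[2])
    want <- oracle_peptide_counts(cs[1], cyclic = cs[2] == "head_to_tail_cyclic")
    expect_equal(formula_string(got), oracle_counts_string(want), label = cs[1])
  }
  expect_equal(formula_string(peptide_formula("G", "linear")), "C2H5NO2")
  expect_equal(formula_string(peptide_formula("TTVTAC", "head_to_tail_cyclic")),
               "C23H40N6O9S")
  expect_error(peptide_formula(""), "empty")
})

test_that("formula arithmetic is element-wise and guards against negatives", {
  a <- parse_formula("C5H8")
  b <- parse_formula("C2H2O")
  expect_equal(formula_string(a + b), "C7H10O")
  expect_equal(formula_string((a + b) - b), "C5H8")
  expect_error(b - a, "negative")
  expect_equal(formula_string(parse_formula("C38H62N6O8S")), "C38H62N6O8S")
  expect_error(parse_formula("C2Zn"), "unsupported element")
})

test_that("apply_spec performs azoline/azole/prenyl arithmetic", {
  base_d <- peptide_formula("TTVTAC", "head_to_tail_cyclic")
  spec_d <- modification_spec(heterocycles = data.frame(pos = 6, state = "azoline"),
                              n_prenyl = 3)
  expect_equal(formula_string(apply_spec(base_d, spec_d, "TTVTAC")),
               "C38H62N6O8S")
  base_e <- peptide_formula("TLSPFC", "head_to_tail_cyclic")
  spec_e <- modification_spec(heterocycles = data.frame(pos = 6, state = "azoline"),
                              n_prenyl = 1)
  expect_equal(formula_string(apply_spec(base_e, spec_e, "TLSPFC")),
               "C35H50N6O7S")
  # azole = azoline plus oxidation (-H2)
  spec_az <- modification_spec(heterocycles = data.frame(pos = 6, state = "azole"))
  azole <- apply_spec(base_d, spec_az, "TTVTAC")
  azoline <- apply_spec(base_d, modification_spec(
    heterocycles = data.frame(pos = 6, state = "azoline")), "TTVTAC")
  expect_equal(formula_string(azoline - azole), "H2")
  # identity under the empty spec
  expect_equal(apply_spec(base_d, modification_spec(), "TTVTAC"), base_d)
  # chemically impossible specs are rejected
  expect_error(apply_spec(base_d, modification_spec(
    heterocycles = data.frame(pos = 3, state = "azoline")), "TTVTAC"),
    "Cys/Ser/Thr")
  expect_error(modification_spec(n_prenyl = -1))
  expect_error(apply_spec(base_d, modification_spec(n_prenyl = 5), "TTVTAC"),
               "exceeds")
})

test_that("monoisotopic m/z agrees with the atom-by-atom oracle", {
  for (f in c("C38H62N6O8S", "C35H50N6O7S", "C43H63N7O8S", "C5H8",
              "C23H40N6O9S", "C11H10N2O")) {
    for (z in c(0L, 1L)) {
      expect_equal(monoisotopic_mz(parse_formula(f), z), oracle_mz(f, z),
                   tolerance = 1e-4, label = paste(f, z))
    }
  }
  expect_equal(monoisotopic_mz(isoprene_formula(), 0L),
               isoprene_neutral_mass_printed, tolerance = 1e-4)
})

test_that("ppm_error matches the standard definition and printed values", {
  expect_equal(round(ppm_error(763.44345, 763.44223), 1), 1.6)
  expect_equal(round(ppm_error(838.45245, 838.45312), 1), -0.8)
  expect_equal(ppm_error(500, 500), 0)
  expect_error(ppm_error(1, 0))
})

test_that("candidate enumeration covers the prenylation/heterocycle space", {
  tl <- enumerate_candidates("TLSPFC", "tru")
  expect_length(tl, 3) # 0, 1, 2 prenyls (Ser+Thr = 2)
  tt <- enumerate_candidates("TTVTAC", "tru")
  expect_length(tt, 4) # 0..3 prenyls
  # every tru candidate has the Cys azoline
  for (p in tt) {
    expect_equal(p$spec$heterocycles$state, "azoline")
    expect_equal(p$spec$heterocycles$pos, 6)
  }
  # no Cys/Ser/Thr: single unmodified macrocycle
  plain <- enumerate_candidates("GAVLFP", "tru")
  expect_length(plain, 1)
  expect_equal(plain[[1]]$formula,
               peptide_formula("GAVLFP", "head_to_tail_cyclic"))
  # pat class: Cys azole mandatory, Ser/Thr azolines, no prenyls
  pat <- enumerate_candidates("TTVTAC", "pat")
  expect_length(pat, 4) # 0..3 Ser/Thr azolines
  expect_true(all(vapply(pat, function(p) p$spec$n_prenyl, numeric(1)) == 0))
})

test_that("isoprene ladders step by exactly one C5H8 per loss", {
  iso <- monoisotopic_mz(isoprene_formula(), 0L)
  for (core in c("TTVTAC", "TLSPFC", "TSIAPFC")) {
    cands <- enumerate_candidates(core, "tru")
    parent <- cands[[length(cands)]] # max prenyl
    lad <- isoprene_ladder(parent)
    expect_equal(nrow(lad), parent$spec$n_prenyl + 1L)
    expect_equal(diff(lad$mz_MH), rep(-iso, parent$spec$n_prenyl),
                 tolerance = 1e-4)
    # conservation: final step equals the directly computed 0-prenyl product
    expect_equal(lad$formula[nrow(lad)], formula_string(cands[[1]]$formula))
  }
  zero <- enumerate_candidates("GAVLFP", "tru")[[1]]
  expect_equal(nrow(isoprene_ladder(zero)), 1L)
})

test_that("match_observed picks the closest candidate and honors tolerance", {
  tt <- enumerate_candidates("TTVTAC", "tru")
  m <- match_observed(763.44345, tt)
  expect_true(m$matched)
  expect_equal(m$candidate$spec$n_prenyl, 3L)
  expect_equal(round(m$ppm, 1), 1.6)
  tl <- enumerate_candidates("TLSPFC", "tru")
  m2 <- match_observed(699.35469, tl)
  expect_true(m2$matched)
  expect_equal(m2$candidate$spec$n_prenyl, 1L)
  expect_equal(round(m2$ppm, 1), 1.8)
  far <- match_observed(500.0, tt)
  expect_false(far$matched)
  expect_null(far$candidate)
})

test_that("report_chem reproduces the worked example end to end", {
  rep <- report_chem(data.frame(core = c("TTVTAC", "TLSPFC", "TSIAPFC"),
                                class = "tru"),
                     observed = c(763.44345, 699.35469, 838.45245))
  expect_equal(rep$matches$ppm, c(1.6, 1.8, -0.8))
  expect_equal(rep$matches$formula,
               c("C38H62N6O8S", "C35H50N6O7S", "C43H63N7O8S"))
  expect_true(all(rep$matches$matched))
  # ladder rows present for each matched peak
  expect_setequal(unique(rep$ladders$peak), c("peak1", "peak2", "peak3"))
})
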