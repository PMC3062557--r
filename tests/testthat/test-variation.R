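# Occupancy calling, crossover profiling, cassette extraction and
# three-level classification against planted truth.

make_pop <- function(seed, occ) {
  simulate_population(small_test_config(seed = seed, occupancy = occ))
}

test_that("loci are located at truth coordinates and occupancy is recovered", {
  occ <- matrix(c("present", "absent", "present",
                  "absent", "present", "present",
                  "present", "residual", "absent"), nrow = 3, byrow = TRUE)
  pop <- make_pop(33, occ)
  for (g in names(pop$genomes)) {
    loc <- locate_loci(pop$genomes[[g]], pop$loci)
    expect_true(all(loc$status == "located"))
    f <- subset(pop$truth$features, genome == g)
    # left flank must end at the insert start, right flank begin at its end
    expect_true(all(abs(loc$left_end - f$start) <= 5))
    expect_true(all(abs(loc$right_start - f$end) <= 5))
    for (j in seq_len(nrow(loc))) {
      call <- call_occupancy(pop$genomes[[g]], loc[j, ],
                             pop$templates[[j]]$seq)
      truth <- occ[match(g, names(pop$genomes)), j]
      expected <- if (truth == "residual") "unresolved" else truth
      expect_equal(call$state, expected,
                   label = paste(g, pop$loci$cluster_id[j]))
      if (truth == "present" && !(j == 3)) {
        expect_gte(call$identity, 0.99)
      }
      if (truth == "residual") {
        # partial-match evidence: some homology seen, wrong length
        expect_gt(call$coverage, 0)
      }
    }
  }
})

test_that("a repeat-embedded flank is flagged repeat-confounded", {
  cfg <- small_test_config(seed = 35, occupancy = matrix("present", 2, 3),
                           n_genomes = 2, repeat_flank_prob = 1)
  pop <- simulate_population(cfg)
  loc <- locate_loci(pop$genomes$g1, pop$loci)
  expect_true(all(loc$status == "repeat-confounded"))
  call <- call_occupancy(pop$genomes$g1, loc[1, ], pop$templates[[1]]$seq)
  expect_equal(call$state, "repeat-confounded")
})

test_that("a genome lacking the flanks entirely is unresolved", {
  pop <- simulate_population(small_test_config(
    seed = 36, n_genomes = 2, occupancy = matrix("present", 2, 3)))
  stranger <- generate_backbone(20000)
  loc <- locate_loci(stranger, pop$loci)
  expect_true(all(loc$status == "unresolved"))
})

test_that("crossover profiles segment the planted swap and localize scars", {
  occ <- matrix("present", 3, 3)
  cfg <- small_test_config(seed = 37, occupancy = occ,
                           crossover_variant_genomes = c(2, 3),
                           crossover_offsets_5 = c(0, 5),
                           crossover_offsets_3 = c(0, 300))
  pop <- simulate_population(cfg)
  cl <- function(g) {
    f <- subset(pop$truth$features, genome == g & cluster_id == "cyano")
    substr(pop$genomes[[g]], f$start + 1, f$end)
  }
  tru_bp <- pop$truth$crossover
  win <- 100L
  divseg <- function(prof) {
    s <- prof$segments
    s[s$state == "diverged" & s$end - s$start >= 500, ]
  }
  p12 <- crossover_profile(cl("g1"), cl("g2"), window = win)
  p13 <- crossover_profile(cl("g1"), cl("g3"), window = win)
  d12 <- divseg(p12); d13 <- divseg(p13)
  expect_equal(nrow(d12), 1)
  expect_equal(nrow(d13), 1)
  # three segments: identical flank, diverged core, identical flank
  expect_gte(nrow(p12$segments), 3)
  expect_lt(d12$identity, 0.77)
  expect_gt(d12$identity, 0.25)
  # breakpoints within one window of planted scars (template coordinates
  # are genome-copy coordinates here because g1 carries the unmodified
  # template copy)
  bp2 <- subset(tru_bp, genome == "g2")
  bp3 <- subset(tru_bp, genome == "g3")
  expect_lte(abs(d12$start - bp2$bp5), win)
  expect_lte(abs(d12$end - bp2$bp3), win)
  expect_lte(abs(d13$start - bp3$bp5), win)
  expect_lte(abs(d13$end - bp3$bp3), win)
  # the 5 bp vs ~300 bp offset pair is recovered within a window
  expect_lte(abs((d13$start - d12$start) - 5), win)
  expect_lte(abs((d13$end - d12$end) - 300), win)
  # identical clusters: a single flank-identical segment
  pself <- crossover_profile(cl("g1"), cl("g1"), window = win)
  expect_equal(nrow(pself$segments), 1)
  expect_equal(pself$segments$state, "flank-identical")
})

test_that("cassette cores are extracted and translated from precursors", {
  cores <- list(cyano = rbind(g1 = c("TTVTAC", "TLSPFC"),
                              g2 = c("TTVTAC", "SYDGVD")))
  cfg <- small_test_config(seed = 39, n_genomes = 2,
                           occupancy = matrix("present", 2, 3),
                           cassette_cores = cores,
                           crossover_variant_genomes = integer(0),
                           crossover_offsets_5 = numeric(0),
                           crossover_offsets_3 = numeric(0))
  pop <- simulate_population(cfg)
  tpl <- pop$templates[[3]]
  lm <- leader_model(tpl)
  f <- subset(pop$truth$features, genome == "g1" & cluster_id == "cyano")
  prec <- substr(pop$genomes$g1, f$start + 1, f$end)
  got <- extract_cores(prec, lm)
  expect_equal(got$aa, c("TTVTAC", "TLSPFC"))
  expect_true(all(nchar(got$dna) <= 30))
  # precursor without cassette motifs: empty with warning
  expect_warning(none <- extract_cores(generate_backbone(2000), lm),
                 "no cassette")
  expect_equal(nrow(none), 0)
})

test_that("variation levels follow the decision rule on planted truth", {
  cores <- list(cyano = rbind(g1 = c("TTVTAC", "TLSPFC"),
                              g2 = c("TTVTAC", "SYDGVD"),
                              g3 = c("TSIAPFC", "TLSPFC")))
  occ <- matrix(c("present", "present", "present",
                  "absent", "present", "present",
                  "present", "absent", "present"), nrow = 3, byrow = TRUE)
  cfg <- small_test_config(seed = 41, occupancy = occ,
                           cassette_cores = cores,
                           crossover_variant_genomes = 3,
                           crossover_offsets_5 = 0,
                           crossover_offsets_3 = 0)
  pop <- simulate_population(cfg)
  gcall <- function(g) {
    loc <- locate_loci(pop$genomes[[g]], pop$loci)
    calls <- do.call(rbind, lapply(seq_len(nrow(loc)), function(j) {
      call_occupancy(pop$genomes[[g]], loc[j, ], pop$templates[[j]]$seq)
    }))
    calls
  }
  calls <- lapply(names(pop$genomes), gcall)
  names(calls) <- names(pop$genomes)
  cl <- function(g, cid) {
    f <- subset(pop$truth$features, genome == g & cluster_id == cid)
    substr(pop$genomes[[g]], f$start + 1, f$end)
  }
  # level 1: nrps occupancy differs between g1 and g2
  v1 <- classify_variation(calls$g1[1, ], calls$g2[1, ])
  expect_equal(v1$levels, 1L)
  # level 2: cyano g1 (template class) vs g3 (crossover variant)
  prof13 <- crossover_profile(cl("g1", "cyano"), cl("g3", "cyano"))
  v2 <- classify_variation(calls$g1[3, ], calls$g3[3, ], profile = prof13)
  expect_true(2L %in% v2$levels)
  # symmetric in the genome pair
  prof31 <- crossover_profile(cl("g3", "cyano"), cl("g1", "cyano"))
  v2r <- classify_variation(calls$g3[3, ], calls$g1[3, ], profile = prof31)
  expect_equal(v2$levels, v2r$levels)
  # level 3: cyano g1 vs g2 — same class, identical except one cassette
  lm <- leader_model(pop$templates[[3]])
  prof12 <- crossover_profile(cl("g1", "cyano"), cl("g2", "cyano"))
  v3 <- classify_variation(calls$g1[3, ], calls$g2[3, ], profile = prof12,
                           coresA = extract_cores(cl("g1", "cyano"), lm),
                           coresB = extract_cores(cl("g2", "cyano"), lm))
  expect_equal(v3$levels, 3L)
  # ribo shared by g1 and g2 with per-genome random cores: level 3 if the
  # cassette draws differ, otherwise no variation at all
  prof_ribo <- crossover_profile(cl("g1", "ribo"), cl("g2", "ribo"))
  lm_ribo <- leader_model(pop$templates[[2]])
  cr1 <- extract_cores(cl("g1", "ribo"), lm_ribo)
  cr2 <- extract_cores(cl("g2", "ribo"), lm_ribo)
  v0 <- classify_variation(calls$g1[2, ], calls$g2[2, ], profile = prof_ribo,
                           coresA = cr1, coresB = cr2)
  if (any(cr1$dna != cr2$dna)) {
    expect_equal(v0$levels, 3L)
  } else {
    expect_equal(v0$levels, 0L)
  }
  # unresolved input propagates
  un <- calls$g1[1, ]; un$state <- "unresolved"
  expect_true(is.na(classify_variation(un, calls$g2[1, ])$levels))
})
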