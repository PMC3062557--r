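# Synteny: anchors, chaining, identity, break classification, contig
# mapping, mate verification and composition classification.

test_that("anchors behave on identity, reverse complement and shuffles", {
  set.seed(14)
  s <- generate_backbone(10000)
  a <- find_anchors(s, s)
  plus <- a[a$strand == "+", ]
  expect_true(any(plus$length == 10000)) # one full-length anchor
  rc <- revcomp(s)
  a2 <- find_anchors(s, rc)
  expect_true(any(a2$strand == "-" & a2$length == 10000))
  # shuffled sequence: shared 15-mers are chance collisions; with 1e4
  # positions each the Poisson expectation is 1e8/4^15 ~ 0.1, so allow a
  # handful at most
  shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  a3 <- find_anchors(s, shuf)
  expect_lt(nrow(a3), 10)
})

test_that("chaining recovers a planted single block and planted insertions", {
  set.seed(15)
  bb <- generate_backbone(20000)
  st <- derive_strain(bb, 0.97)
  blocks <- chain_and_extend(find_anchors(bb, st$seq), bb, st$seq)
  expect_equal(nrow(blocks), 1)
  expect_lt(abs(blocks$identity - 0.97), 0.005)
  # plant a 10 kbp cassette present only in the reference
  cassette <- generate_backbone(10000)
  ref2 <- paste0(substr(bb, 1, 10000), cassette, substr(bb, 10001, 20000))
  blocks2 <- chain_and_extend(find_anchors(ref2, st$seq), ref2, st$seq)
  expect_equal(nrow(blocks2), 2)
  br <- classify_breaks(blocks2)
  expect_equal(br$class, "cassette-candidate")
  expect_lt(abs(br$ref_gap - 10000), 50)
  expect_lt(abs(br$qry_gap), 50)
  # empty anchors give empty blocks
  expect_equal(nrow(chain_and_extend(
    find_anchors("ACGTACGTACGTACGTACGT", generate_backbone(1000), k = 15),
    "ACGTACGTACGTACGTACGT", "AAAA")), 0)
})

test_that("identity estimates agree with the quadratic alignment oracle", {
  set.seed(16)
  for (target in c(0.95, 0.97, 0.99)) {
    bb <- generate_backbone(4000)
    st <- derive_strain(bb, target)
    cmp <- compare_genomes(bb, st$seq)
    expect_lt(abs(cmp$ani - oracle_identity(bb, st$seq)), 0.01,
              label = paste("target", target))
  }
})

test_that("ANI is symmetric and ordered by configured relatedness", {
  cfg <- population_config(n_genomes = 3, backbone_length = 30000,
                           divergence = c(0.02, 0.01, 0.01),
                           occupancy = matrix("absent", 3, 5), seed = 31)
  pop <- simulate_population(cfg)
  ab <- compare_genomes(pop$genomes$g1, pop$genomes$g2)
  ba <- compare_genomes(pop$genomes$g2, pop$genomes$g1)
  expect_lt(abs(ab$ani - ba$ani), 0.002) # symmetry
  bc <- compare_genomes(pop$genomes$g2, pop$genomes$g3)
  # g2 and g3 (1% each from the ancestor) are closer to each other than
  # either is to g1 (2%)
  expect_gt(bc$ani, ab$ani)
  ac <- compare_genomes(pop$genomes$g1, pop$genomes$g3)
  expect_gt(bc$ani, ac$ani)
  expect_error(average_identity(data.frame()), "block")
})

test_that("self-comparison is perfect", {
  set.seed(18)
  s <- generate_backbone(15000)
  cmp <- compare_genomes(s, s)
  expect_equal(cmp$ani, 1.0)
  expect_equal(cmp$coverage, 1.0)
})

test_that("contigs map back to their true offsets; aliens stay unplaced", {
  cfg <- small_test_config(seed = 19, n_genomes = 2,
                           occupancy = matrix("present", 2, 3))
  pop <- simulate_population(cfg)
  set.seed(42)
  fm <- fragment_with_mates(pop$genomes$g2, N50 = 8000, genome_id = "g2")
  pl <- map_contigs(pop$genomes$g2, fm$contigs)
  placed <- pl[pl$status == "placed", ]
  big <- fm$contigs[fm$contigs$end - fm$contigs$start >= 1000, ]
  expect_gte(nrow(placed) / nrow(big), 0.95)
  truth_start <- fm$contigs$start[match(placed$contig, fm$contigs$contig)]
  expect_true(all(abs(placed$ref_start - truth_start) <= 10))
  # an unrelated random contig cannot be placed
  alien <- data.frame(contig = "alien", seq = generate_backbone(5000))
  expect_equal(map_contigs(pop$genomes$g2, alien)$status, "unplaced")
  # a pure repeat contig is flagged ambiguous
  unit <- generate_backbone(2000)
  host <- paste0(generate_backbone(4000), unit, generate_backbone(4000),
                 unit, generate_backbone(4000))
  rep_ctg <- data.frame(contig = "rep", seq = unit)
  expect_equal(map_contigs(host, rep_ctg)$status, "ambiguous")
})

test_that("mate links verify contig order and flag artificial swaps", {
  cfg <- small_test_config(seed = 23, n_genomes = 2,
                           occupancy = matrix("absent", 2, 3),
                           backbone_length = 60000)
  pop <- simulate_population(cfg)
  set.seed(7)
  fm <- fragment_with_mates(pop$genomes$g1, N50 = 6000,
                            insert_mean = 3000, insert_sd = 300,
                            n_mates = 500, genome_id = "g1")
  pl <- map_contigs(pop$genomes$g1, fm$contigs)
  rep <- verify_order_with_mates(pl, fm$mates)
  expect_gte(rep$concordant_fraction, 0.99)
  # swap two adjacent placed contigs: links across the swap turn discordant
  pl2 <- pl
  i <- which(pl2$status == "placed")[2:3]
  tmp <- pl2$ref_start[i[1]]
  width1 <- pl2$ref_end[i[1]] - pl2$ref_start[i[1]]
  width2 <- pl2$ref_end[i[2]] - pl2$ref_start[i[2]]
  pl2$ref_start[i[1]] <- pl2$ref_start[i[2]] + width2 - width1
  pl2$ref_end[i[1]] <- pl2$ref_start[i[1]] + width1
  pl2$ref_start[i[2]] <- tmp
  pl2$ref_end[i[2]] <- tmp + width2
  rep2 <- verify_order_with_mates(pl2, fm$mates)
  expect_lt(rep2$concordant_fraction, rep$concordant_fraction)
  cross <- rep2$links$class[rep2$links$contig1 == pl$contig[i[1]] &
                             rep2$links$contig2 == pl$contig[i[2]]]
  expect_true(all(cross == "discordant"))
  # no links: empty report
  empty <- verify_order_with_mates(pl, fm$mates[0, ])
  expect_true(is.na(empty$concordant_fraction))
})

test_that("composition classifier separates GC-shifted contaminants", {
  set.seed(27)
  sym <- generate_backbone(80000)
  # contaminant with strongly shifted composition
  contam <- paste(sample(c("A", "C", "G", "T"), 80000, replace = TRUE,
                         prob = c(0.15, 0.35, 0.35, 0.15)), collapse = "")
  refs <- list(symbiont = substr(sym, 1, 40000),
               contaminant = substr(contam, 1, 40000))
  grab <- function(src, n, len, label) {
    starts <- floor(runif(n, 40000, 80000 - len))
    data.frame(contig = paste0(label, seq_len(n)),
               seq = vapply(starts, function(s) substr(src, s, s + len - 1),
                            character(1)),
               truth = label)
  }
  ctgs <- rbind(grab(sym, 20, 5000, "symbiont"),
                grab(contam, 20, 5000, "contaminant"))
  cls <- classify_contigs_by_composition(ctgs, refs)
  expect_gte(mean(cls$label == ctgs$truth), 0.95)
  # a contig identical to a centroid source gets that label
  self <- data.frame(contig = "self", seq = refs$symbiont)
  expect_equal(classify_contigs_by_composition(self, refs)$label, "symbiont")
  # short contigs are low confidence
  tiny <- data.frame(contig = "tiny", seq = substr(sym, 1, 500))
  expect_true(classify_contigs_by_composition(tiny, refs)$low_confidence)
})
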