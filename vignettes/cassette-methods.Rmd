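---
title: "Methods: cassette-level variation in clonal symbiont genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cassette-level variation in clonal symbiont genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models and numerical
choices: what each stage assumes, which tunable parameters matter and why
their defaults are what they are, what the synthetic data generator does and
does not emulate, and where the genuinely open design decisions were made.

# The system being modelled

A clonal population of photosynthetic bacterial symbionts living in
tropical ascidians. Strains sampled across thousands of kilometres are
>97% identical over most of the chromosome; nearly all functional
differences concentrate in secondary-metabolite gene clusters that sit at
fixed integration loci, flanked by highly conserved genes. A shared
cluster is >99–100% identical between strains. Variation occurs at three
scales: whole-cluster presence/absence, an internal "crossover" swap that
exchanges a ~4.5 kbp enzymatic region inside an ~11 kbp cyanobactin
operon (divergence 25–77% between the two functional classes), and
hypervariable ≤30 bp core cassettes inside otherwise identical precursor
peptide genes. The cyanobactin products themselves are head-to-tail
macrocyclic peptides whose mass is exactly predictable from the core
sequence and a modification state.

# Product chemistry

A peptide formula is the element-wise sum of residue formulas; a linear
peptide adds one water (free termini), a head-to-tail macrocycle does not.
Modifications are pure formula arithmetic:

* azoline heterocycle (Cys/Ser/Thr side chain cyclized onto the backbone):
  −H₂O;
* azole (oxidized azoline): an additional −H₂;
* prenylation (isoprene on a Ser/Thr hydroxyl): +C₅H₈ per site.

Monoisotopic element masses are fixed constants (C 12, H 1.00782503,
N 14.00307401, O 15.99491462, S 31.97207069; proton 1.00727646), chosen to
reproduce published FT-ICR values to ≤5×10⁻⁵ Da. Predicted masses are
reported as singly protonated [M+H]⁺, 5 decimals; ppm errors
((obs−pred)/pred × 10⁶) to one decimal. These conventions match how
high-resolution MS data for this compound class are printed.

Candidate enumeration encodes the two pathway classes: the prenylating
class forms the azoline only at Cys and attaches 0..(#Ser+#Thr) isoprenes;
the heterocyclizing class oxidizes Cys to the azole and may convert any
number of Ser/Thr to azolines, without prenylation. MS cannot localize a
prenyl group among equivalent Ser/Thr sites, so candidates are
deduplicated by molecular formula, prenyl *sites* stay optional in the
data model, and matching minimizes |ppm| with ties broken toward fewer
modifications (default tolerance 5 ppm, typical for FT-ICR work).

One documented quirk: the published −1-isoprene fragment formula for the
trunkamide standard is internally inconsistent with its own printed mass;
the mass corresponds to C₃₈H₅₅N₇O₈S (the parent C₄₃H₆₃N₇O₈S minus C₅H₈),
which is what the package computes. Several printed fragment Δppm figures
also fail to recompute from their own printed mass pairs (a transposed
pair, a dropped digit, a sign flip); the tests therefore assert the Δ
implied by the printed masses rather than the misprinted Δ column.

# The synthetic population generator

The generator emits the stated world of the analysis, not a tuned one: a
single ancestral backbone (uniform base composition); per-strain divergence
applied as uniformly placed mutation events (95% substitutions, 5% indels
with geometric lengths, mean 2 bp — the indel share is a modelling choice,
as inter-strain indel content is not quantified in the source system);
conserved flanking genes modelled as mutation-free windows (default 300 bp)
on each side of every integration locus; clusters inserted at 0-based
insertion points per an occupancy matrix, each copy receiving ~0.3%
substitutions so shared copies sit in the stated >99% identity band;
a crossover variant whose central region is replaced by a 50%-identity
alternative with per-genome breakpoint offsets (defaults 0/5 bp at the 5'
junction and 0/300 bp at the 3' junction, the configuration actually
observed between the two sequenced variant strains); precursor genes whose
leader and recognition motifs are conserved while ≤30 bp cassettes vary
per genome; optional multi-copy repeat elements that *replace* locus
flanks, to exercise the known failure mode of junction-spanning primer
design; and gap-free fragmentation with mate pairs (insert 3000 ± 300 bp
by default; contig lengths Uniform(0.5c, 1.5c) with c = N50/1.118, which
makes the realized N50 land within a few percent of target).

Default scale is 30–50 kbp backbones with 6–11 kbp clusters: three orders
of magnitude below the real ~6 Mbp chromosomes, but preserving every
structural relationship the callers rely on (cluster ≫ max PCR product ≫
junction tolerance; flank ≫ primer length). A green test therefore
establishes the *logic* of each caller, not its robustness to real-data
pathologies the generator does not emulate: sequencing error, collapsed
assemblies, chimeric contigs, non-uniform composition, gene-scale
selection, or multiple strains per sample.

All coordinates in truth tables and emitted files are 0-based half-open,
forward strand only; one RNG stream per run makes output byte-identical
per seed.

# Synteny and ANI

Seed–chain–extend at desk scale: maximal exact k-mer anchors (k = 15,
k-mers occurring more than 5 times masked as repeats), windowed
co-linear chaining (score = anchored bases, gaps ≤ 5 kbp, small anchor
overlaps tolerated and charged against the score), chains split into
blocks where either genome jumps by more than 200 bp, and identity per
block computed from anchored bases plus global alignment of the small
inter-anchor gaps (equal-length gaps ≤50 bp by direct comparison; the
alignment primitive is Biostrings' pairwiseAlignment with a fixed scoring
scheme). ANI is the block-length-weighted mean identity; coverage is the
anchored fraction of the reference. At 97% identity this estimator agrees
with full quadratic global alignment to ~0.1–0.2 identity points
(verified against that oracle in the tests on ≤5 kbp instances, bound
0.01).

Inter-block gaps are classified by the rule a human applies to a genome
comparison view: one-sided gap ≥2 kbp with ≤200 bp on the other genome →
cassette candidate (insertion/deletion at a locus); both sides large, or
out-of-order blocks → rearrangement or misassembly; gaps at contig
termini → uninformative. Note that ANI on cluster-bearing genomes is a
mixture of backbone identity and >99%-identical shared clusters; the
ANI-recovery acceptance test therefore runs on populations with all loci
empty, where the configured backbone identity is the estimand.

# Occupancy calling and the three levels

A locus is located by exact/near-exact (≤2% mismatch) unique placement of
both conserved flanks; multiple placements flag it repeat-confounded. With
both flanks placed: inter-flank distance ≤50 bp → **absent** (the
tolerance admits small scars while keeping genuine residual fragments —
e.g. a single leftover gene from a lost cluster — out of the absent
class); distance within 20% of the reference cluster length, anchored
coverage ≥0.5 and anchored identity ≥0.9 → **present**; anything else →
**unresolved**. Coverage 0.5 rather than ~1 is deliberate: a homologous
pathway variant whose central ~40% has crossed over still occupies the
locus and must call present.

Variation levels follow an explicit decision rule (the schematic source
figure does not fix thresholds): level 1 iff occupancy differs; level 2
iff a shared cluster has an internal segment ≥500 bp below 0.90 identity
with a flanking segment ≥0.99; level 3 iff identity is ≥0.99 everywhere
except diverged stretches no longer than a cassette plus window blur
(30 + 2×window bp) and the extracted cassettes differ. Windowed profiles
(window 100 bp, step 20 bp) are segmented by anchor-coverage
thresholds, each segment's identity is then refined by alignment of the
corresponding subsequences (anchor coverage alone underestimates identity
where mismatches cluster), adjacent same-state segments are merged, and
each high/low boundary is refined to the end of the last (start of the
first) exact anchor near the coarse transition — this pins breakpoints to
a few bases, well inside the one-window acceptance tolerance. A
consequence of the strict level-3 rule: two crossover variants with
*different* scar offsets differ over a few hundred bases at the scar, so
that pair is neither level 2 (too short) nor level 3 (too long); it is
reported as level 0 with the scar visible in the profile. This is the
honest reading of the rule, and the demo documents it.

# In-silico PCR and the co-occurrence statistic

Primer design is sequence-logic only (length 20, GC 40–60%, exact-match
uniqueness across the genome set); thermodynamics are out of scope because
the assay system functions as a presence/absence logic device. The
presence assay is internal to the cluster; the absence assay spans the
empty junction and cannot amplify across an inserted cluster because all
clusters exceed the 5 kbp product ceiling — that inequality is the design
premise, and the generator's default cluster sizes respect it. Virtual
PCR allows one mismatch per primer but none in the 3'-terminal 3 nt.
Both-negative is reported unresolved (absence is a positive junction
amplification, not a failure to amplify); both-positive is a hard error.

Pathway co-occurrence is tested against a fixed-margin permutation null
(each pathway's labels permuted independently across samples, preserving
prevalences exactly). The p-value is the add-one **mid-p** of the absolute
deviation of co-presence counts from the null mean. The plain two-sided
add-one p is markedly conservative here — co-presence counts over ~24
samples take few distinct values, and the measured false-positive rate at
nominal 5% was 1–2%; the mid-p form restores calibration to ~4–5%
(measured before the calibration test was frozen). Pairs with a
degenerate column are skipped with a note.

# Known limitations

* The generator is forward-strand only; inversions and translocations are
  detected (as rearrangement breaks) but never planted.
* Sequencing error, coverage variation and assembly artefacts are not
  modelled; contig fragmentation is gap-free.
* Primer design does not model melting temperature, dimers, or degenerate
  bases; "impractical" is a sequence-uniqueness verdict only.
* The crossover profile reports window-resolution segments; sub-window
  events (< ~20 bp) inside a diverged region are invisible.
* Mass prediction covers CHNOS chemistry, singly protonated ions and
  whole-isoprene neutral losses; isotope patterns, multiple charging and
  other adducts are out of scope.
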