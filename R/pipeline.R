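# End-to-end pipeline: generate -> compare -> call -> genotype -> predict
# chemistry, with a run manifest for reproducibility.

#' Demo population configuration
#'
#' Three genomes mirroring the structure of the three deeply sequenced
#' samples: a reference strain carrying the heterocyclizing (pat-like)
#' cyanobactin cluster, and two strains carrying the prenylating (tru-like)
#' variant with crossover scars offset by 5 bp (5') and ~300 bp (3').
#' Cassette cores include published cyanobactin core sequences (TTVTAC and
#' TLSPFC, the mollamide D/E cores, and TSIAPFC, trunkamide).
#'
#' @param seed Integer RNG seed.
#' @param backbone_length Backbone length (bp).
#' @return A [population_config()].
#' @export
demo_config <- function(seed = 1, backbone_length = 50000) {
  occ <- matrix(c(
    # nrps   pks       terpene   ribo      cyano
    "present", "absent", "present", "present", "present",  # g1 (P1-like)
    "present", "absent", "present", "present", "present",  # g2 (P2-like)
    "present", "present", "absent", "residual", "present"  # g3 (P3-like)
  ), nrow = 3, byrow = TRUE)
  cores <- list(cyano = rbind(
    g1 = c("ITACIT", NA),
    g2 = c("TTVTAC", "TLSPFC"),
    g3 = c("TSIAPFC", NA)
  ))
  population_config(
    n_genomes = 3, backbone_length = backbone_length,
    divergence = c(0.02, 0.01, 0.01), # g2,g3 closer to each other than to g1
    occupancy = occ,
    crossover_variant_genomes = c(2, 3),
    crossover_offsets_5 = c(0, 5),
    crossover_offsets_3 = c(0, 300),
    cassette_cores = cores,
    seed = seed)
}

#' Leader model of a precursor gene from a cluster template
#'
#' @param template A realized `cluster_template` (with sequence) carrying a
#'   precursor.
#' @return List with `pre_motifs` and `post_motifs` for [extract_cores()].
#' @export
leader_model <- function(template) {
  if (is.null(template$precursor)) stop("template has no precursor gene")
  list(pre_motifs = template$precursor$pre_motifs,
       post_motifs = template$precursor$post_motifs)
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Stages: population generation, pairwise synteny/ANI, locus occupancy
#' calling, three-level variation classification, in-silico PCR genotype
#' matrix with co-occurrence statistics, and cyanobactin product prediction
#' from extracted precursor cores matched against observed peaks.
#'
#' @param config A [population_config()] (default [demo_config()]).
#' @param observed_peaks Numeric vector of observed `[M+H]+` values to match
#'   against predicted products.
#' @param outdir Optional directory; when given, all tables are written as
#'   TSV/JSON plus per-genome FASTA, and a manifest records the run.
#' @return List with `population`, `ani` (pairwise table), `locus_calls`,
#'   `variation` (per cluster and genome pair), `pcr` (genotype matrix and
#'   co-occurrence), `chem` (product report), `manifest`.
#' @export
run_all <- function(config = demo_config(), observed_peaks = numeric(0),
                    outdir = NULL) {
  timings <- c()
  tick <- function(expr) {
    t0 <- Sys.time()
    val <- force(expr)
    list(val = val, secs = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  st <- tick(simulate_population(config))
  pop <- st$val
  timings["generate"] <- st$secs

  gn <- names(pop$genomes)
  st <- tick({
    pairs <- utils::combn(gn, 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      cmp <- compare_genomes(pop$genomes[[a]], pop$genomes[[b]])
      data.frame(ref = a, qry = b, ani = cmp$ani, coverage = cmp$coverage,
                 n_blocks = nrow(cmp$blocks),
                 n_cassette_breaks = sum(cmp$breaks$class == "cassette-candidate"),
                 stringsAsFactors = FALSE)
    }))
  })
  ani <- st$val
  timings["synteny"] <- st$secs

  st <- tick({
    do.call(rbind, lapply(gn, function(g) {
      loc <- locate_loci(pop$genomes[[g]], pop$loci)
      calls <- do.call(rbind, lapply(seq_len(nrow(loc)), function(j) {
        call_occupancy(pop$genomes[[g]], loc[j, ], pop$templates[[j]]$seq)
      }))
      if (is.null(calls)) return(NULL)
      calls$genome <- g
      calls
    }))
  })
  locus_calls <- st$val
  timings["occupancy"] <- st$secs

  cluster_seq <- function(g, cid) {
    f <- pop$truth$features
    r <- f[f$genome == g & f$cluster_id == cid, ]
    substr(pop$genomes[[g]], r$start + 1L, r$end)
  }
  st <- tick({
    rows <- list()
    for (j in seq_along(pop$templates)) {
      tpl <- pop$templates[[j]]
      lm <- if (!is.null(tpl$precursor)) leader_model(tpl) else NULL
      pairs <- utils::combn(gn, 2)
      for (i in seq_len(ncol(pairs))) {
        a <- pairs[1, i]; b <- pairs[2, i]
        ca <- locus_calls[locus_calls$genome == a &
                            locus_calls$locus_id == pop$loci$locus_id[j], ]
        cb <- locus_calls[locus_calls$genome == b &
                            locus_calls$locus_id == pop$loci$locus_id[j], ]
        prof <- NULL; coresA <- NULL; coresB <- NULL
        if (nrow(ca) && nrow(cb) &&
            ca$state == "present" && cb$state == "present") {
          sa <- cluster_seq(a, tpl$id)
          sb <- cluster_seq(b, tpl$id)
          prof <- crossover_profile(sa, sb)
          if (!is.null(lm)) {
            coresA <- suppressWarnings(extract_cores(sa, lm))
            coresB <- suppressWarnings(extract_cores(sb, lm))
          }
        }
        vc <- classify_variation(ca, cb, profile = prof,
                                 coresA = coresA, coresB = coresB)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = tpl$id, genome1 = a, genome2 = b,
          levels = paste(vc$levels, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  variation <- st$val
  timings["variation"] <- st$secs

  st <- tick({
    bm <- build_matrix(pop$genomes, pop$loci, pop$templates,
                       truth = pop$truth$occupancy)
    co <- tryCatch(cooccurrence_test(bm$matrix, seed = config$seed),
                   error = function(e) NULL)
    list(matrix = bm$matrix, prevalence = bm$prevalence,
         recovery = bm$recovery, cooccurrence = co)
  })
  pcr <- st$val
  timings["pcr"] <- st$secs

  st <- tick({
    cyano <- Filter(function(t) identical(t$kind, "cyanobactin"),
                    pop$templates)
    core_tab <- NULL
    if (length(cyano)) {
      tpl <- cyano[[1]]
      lm <- leader_model(tpl)
      rows <- list()
      for (g in gn) {
        if (pop$truth$occupancy[g, tpl$id] != "present") next
        cls <- if (match(g, gn) %in% config$crossover_variant_genomes)
          "tru" else "pat"
        cores <- suppressWarnings(extract_cores(cluster_seq(g, tpl$id),
                                                leader_model(tpl)))
        if (nrow(cores)) {
          rows[[length(rows) + 1L]] <- data.frame(
            genome = g, core = cores$aa, class = cls,
            stringsAsFactors = FALSE)
        }
      }
      core_tab <- do.call(rbind, rows)
    }
    if (!is.null(core_tab) && nrow(core_tab)) {
      rep <- report_chem(core_tab[, c("core", "class")], observed_peaks)
      rep$cores <- core_tab
      rep
    } else NULL
  })
  chem <- st$val
  timings["chem"] <- st$secs

  manifest <- list(seed = config$seed,
                   n_genomes = config$n_genomes,
                   backbone_length = config$backbone_length,
                   stage_seconds = as.list(round(timings, 3)))

  result <- list(population = pop, ani = ani, locus_calls = locus_calls,
                 variation = variation, pcr = pcr, chem = chem,
                 manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_population(pop, file.path(outdir, "population"))
    utils::write.table(ani, file.path(outdir, "ani.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(locus_calls, file.path(outdir, "locus_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(variation, file.path(outdir, "variation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(pcr$matrix),
                       file.path(outdir, "genotype_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(pcr$cooccurrence)) {
      utils::write.table(pcr$cooccurrence,
                         file.path(outdir, "cooccurrence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(chem)) {
      utils::write.table(chem$products, file.path(outdir, "chem_products.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(chem$matches)) {
        utils::write.table(chem$matches, file.path(outdir, "chem_matches.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    cfg_file <- file.path(outdir, "config.json")
    cfg_plain <- config
    cfg_plain$cluster_library <- lapply(cfg_plain$cluster_library,
                                        function(t) t[c("id", "kind", "length")])
    jsonlite::write_json(cfg_plain, cfg_file, auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
    manifest$config_md5 <- unname(tools::md5sum(cfg_file))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}

#' Command-line interface
#'
#' Subcommands: `generate` (write a synthetic population), `chem` (predict
#' products for a core and match an observed mass), `run-all` (full
#' pipeline).
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the subcommand's result. Output goes to stdout/files.
#' @export
cassette_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cassette <command> [options]",
    "  generate --seed <int> --out <dir>",
    "  synteny --ref <fasta> --qry <fasta>",
    "  chem --core <AA> --class <tru|pat> [--observed <mz>]",
    "  run-all --seed <int> --out <dir>", sep = "\n")
  if (!length(args)) {
    message(usage)
    return(invisible(NULL))
  }
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cmd <- args[1]
  if (cmd == "generate") {
    cfg <- demo_config(seed = as.integer(opt("seed", "1")))
    pop <- simulate_population(cfg)
    out <- opt("out", "population_out")
    write_population(pop, out)
    message("population written to ", out)
    return(invisible(pop))
  }
  if (cmd == "synteny") {
    ref <- opt("ref"); qry <- opt("qry")
    if (is.null(ref) || is.null(qry)) stop(usage)
    rs <- as.character(Biostrings::readDNAStringSet(ref)[[1]])
    qs <- as.character(Biostrings::readDNAStringSet(qry)[[1]])
    cmp <- compare_genomes(rs, qs)
    message(sprintf("ANI %.4f over %.1f%% of the reference",
                    cmp$ani, 100 * cmp$coverage))
    utils::write.table(cmp$blocks, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (nrow(cmp$breaks)) {
      utils::write.table(cmp$breaks, stdout(), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    return(invisible(cmp))
  }
  if (cmd == "chem") {
    core <- opt("core")
    if (is.null(core)) stop(usage)
    cands <- enumerate_candidates(core, opt("class", "tru"))
    obs <- opt("observed")
    rep <- report_chem(data.frame(core = core,
                                  class = opt("class", "tru")),
                       if (!is.null(obs)) as.numeric(obs) else numeric(0))
    utils::write.table(rep$products, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(rep$matches)) {
      utils::write.table(rep$matches, stdout(), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    return(invisible(rep))
  }
  if (cmd == "run-all") {
    res <- run_all(demo_config(seed = as.integer(opt("seed", "1"))),
                   observed_peaks = c(763.44345, 699.35469, 838.45245),
                   outdir = opt("out", "cassette_out"))
    message("pipeline outputs written; stages (s): ",
            paste(names(res$manifest$stage_seconds),
                  unlist(res$manifest$stage_seconds),
                  sep = "=", collapse = " "))
    return(invisible(res))
  }
  stop(usage)
}
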