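# End-to-end "rediscovery" pipeline on synthetic data, plus the CLI
# dispatcher. Logging goes to stderr via message(); results go to files.

#' Combine two beta matrices over identical probes
#'
#' @param a,b [beta_matrix()] objects with identical probe sets.
#' @return A [beta_matrix()] stacking the subjects of `a` and `b`.
#' @export
combine_beta <- function(a, b) {
  stopifnot(inherits(a, "beta_matrix"), inherits(b, "beta_matrix"))
  if (!identical(a$probes$probe_id, b$probes$probe_id))
    stop("beta matrices have different probe sets")
  beta_matrix(a$probes, rbind(a$values, b$values),
              c(a$subjects, b$subjects))
}

#' Run the full discovery pipeline on simulated data
#'
#' Mirrors the discovery arc on one seeded synthetic world: epigram calling
#' of the mono-allelic epimutation, methylome MVP scan and control-cohort
#' carrier screen with allele-frequency bound, adjacent-probe epi-LD and
#' epi-haplotype blocks, trio annotation scan, variant co-segregation, and
#' antisense readthrough detection. All stage outputs are written under
#' `out_dir` together with a machine-readable `summary.json`
#' (`schema_version` 1).
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed, used for every source of randomness.
#' @param config a [sim_config()]; defaults to the stated-world defaults
#'   with `readthrough_frac = 0.5` (a case-like library).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         config = sim_config(seed = seed,
                                             readthrough_frac = 0.5)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) message("[", name, "] running")

  stage("simulate-locus")
  locus <- gen_locus(config)
  write_fasta_seqs(stats::setNames(locus$ref$seq, "region"),
                   file.path(out_dir, "region.fa"))
  write_gff3(locus$genes, file.path(out_dir, "trio_genes.gff3"))
  write_bed(locus$island, file.path(out_dir, "islands.bed"))

  stage("epigram")
  clones <- gen_clones(locus, config = config)
  write_fasta_seqs(clones$seqs, file.path(out_dir, "clones.fa"))
  calls <- Map(function(s, id) call_clone(s, locus$ref, clone_id = id),
               clones$seqs, names(clones$seqs))
  epigram <- assemble_epigram(unname(calls), locus$ref)
  write_epigram(epigram, file.path(out_dir, "epigram.tsv"))
  epi_call <- call_monoallelic_epimutation(epigram)
  write_json_report(epi_call, file.path(out_dir, "epimutation_call.json"))

  stage("methylome")
  cohort <- gen_beta_cohort(config)
  write_beta_matrix(cohort$controls, file.path(out_dir, "controls.tsv"))
  write_beta_matrix(cohort$cases, file.path(out_dir, "cases.tsv"))
  writeLines(cohort$block_probes, file.path(out_dir, "block_probes.txt"))
  mvp <- mvp_scan(cohort$cases, cohort$controls)
  write_tsv(mvp, file.path(out_dir, "mvp.tsv"))
  carriers <- detect_carriers(cohort$controls, cohort$block_probes)
  af <- allele_frequency(length(carriers$carriers), carriers$n_subjects)
  write_json_report(list(block_probes = carriers$block_probes,
                         carriers = carriers$carriers,
                         n_subjects = carriers$n_subjects,
                         allele_frequency_estimate = af$estimate,
                         allele_frequency_upper_bound = af$upper_bound),
                    file.path(out_dir, "carriers.json"))

  stage("epild")
  combined <- combine_beta(cohort$controls, cohort$cases)
  profile <- adjacent_ld_profile(combined, method = "both")
  write_tsv(profile, file.path(out_dir, "epild_profile.tsv"))
  blocks <- build_blocks(profile)
  utils::write.table(ld_matrix(profile), file.path(out_dir, "epild_r2.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  stage("trioscan")
  ann <- gen_annotation(config)
  trios <- find_trios(ann$genes, ann$islands)
  write_tsv(trios, file.path(out_dir, "trios.tsv"))
  counts <- summarize_patterns(trios)
  locus_trios <- find_trios(locus$genes, locus$island)

  stage("segregation")
  vars <- gen_variants(config)
  write_tsv(vars$variants, file.path(out_dir, "variants.tsv"))
  write_tsv(data.frame(sample = names(vars$status),
                       status = unname(vars$status)),
            file.path(out_dir, "status.tsv"))
  seg <- cosegregate(filter_variants(vars$variants), vars$status)
  write_tsv(seg, file.path(out_dir, "segregating.tsv"))

  stage("antisense")
  reads <- gen_reads(locus, config)
  write_bed(reads, file.path(out_dir, "reads.bed"))
  rt <- if (nrow(locus_trios) > 0)
    detect_readthrough(reads, locus_trios[1, ], locus$genes)
  else NULL
  cls <- classify_reads(reads, locus$genes)
  write_tsv(cls$per_gene, file.path(out_dir, "read_counts.tsv"))
  r3 <- locus$genes[[3]]
  splice <- acceptor_disruption(r3, r3$exons$end[1])  # acceptor -1, intron 5

  summary <- list(
    schema_version = 1L,
    seed = seed,
    epimutation = list(call = epi_call$call,
                       fractions = as.list(epi_call$fractions)),
    mvp = list(n_probes = nrow(mvp), n_flagged_hyper = sum(mvp$flag_hyper)),
    carriers = list(n = length(carriers$carriers),
                    ids = carriers$carriers,
                    allele_frequency = af$estimate,
                    allele_frequency_bound = af$upper_bound),
    epild = list(n_pairs = nrow(profile), n_blocks = length(blocks),
                 block_sizes = vapply(blocks, function(b)
                   length(b$probes), integer(1))),
    trios = list(locus_pattern = if (nrow(locus_trios)) locus_trios$pattern[1]
                 else NA_character_,
                 annotation_counts = stats::setNames(as.list(counts$n),
                                                     counts$pattern)),
    segregation = list(n_segregating = nrow(seg),
                       keys = if (nrow(seg)) sprintf("%s:%d:%s:%s", seg$chrom,
                                                     seg$pos, seg$ref,
                                                     seg$alt) else character(0),
                       planted = vars$truth$key),
    readthrough = if (!is.null(rt))
      list(is_readthrough = rt$is_readthrough,
           antisense_fraction = rt$antisense_fraction_f2,
           contiguous = rt$contiguous_with_r3) else NULL,
    splice_consequence = splice[c("hit", "intron_index", "predicted")])
  write_json_report(summary, file.path(out_dir, "summary.json"))
  message("[done] summary written to ", file.path(out_dir, "summary.json"))
  invisible(summary)
}

# --- minimal CLI -----------------------------------------------------------

cli_parse_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

cli_help <- function() {
  cat("usage: epitrio <subcommand> [--options]\n",
      "subcommands:\n",
      "  run-all   --out DIR [--seed N] [--readthrough-frac X]\n",
      "  simulate  --what locus|clones|cohort|reads|annotation|variants\n",
      "            --out DIR [--seed N]\n",
      "  epigram   --clones FASTA --ref FASTA --snp-offset N\n",
      "            --snp-alleles G,T --out DIR\n",
      "  mvp       --cases TSV --controls TSV --out DIR [--delta 0.3]\n",
      "  carriers  --cohort TSV --block FILE --out DIR\n",
      "  epild     --cohort TSV --out DIR [--method both] [--r2-min 0.8]\n",
      "  trioscan  --genes GFF3 --islands BED --out DIR [--window 1000]\n",
      "  antisense --reads BED --genes GFF3 --islands BED --out DIR\n",
      "  segregate --variants TSV --status TSV --out DIR [--maf-max 0.001]\n",
      sep = "")
}

#' Command-line entry point
#'
#' Dispatches the `epitrio` subcommands (`run-all`, `simulate`, `epigram`,
#' `mvp`, `carriers`, `epild`, `trioscan`, `antisense`, `segregate`).
#' Intended to be called from the launcher script in
#' `system.file("cli", "epitrio", package = "epitrio")`; logging goes to
#' stderr, results to files under `--out`.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
epitrio_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("--help", "-h", "help")) {
    cli_help()
    return(invisible(0L))
  }
  sub <- args[1]
  opts <- cli_parse_opts(args[-1])
  need <- function(key) {
    if (is.null(opts[[key]]))
      stop("subcommand '", sub, "' requires --", key)
    opts[[key]]
  }
  seed <- as.integer(if (is.null(opts$seed)) 1 else opts$seed)
  out <- if (!is.null(opts$out)) {
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    opts$out
  }
  status <- 0L
  switch(sub,
    "run-all" = {
      cfg <- sim_config(seed = seed,
                        readthrough_frac =
                          as.numeric(if (is.null(opts[["readthrough-frac"]]))
                                     0.5 else opts[["readthrough-frac"]]))
      run_pipeline(need("out"), seed = seed, config = cfg)
    },
    simulate = {
      cfg <- sim_config(seed = seed)
      what <- need("what")
      out <- need("out")
      switch(what,
        locus = {
          locus <- gen_locus(cfg)
          write_fasta_seqs(stats::setNames(locus$ref$seq, "region"),
                           file.path(out, "region.fa"))
          write_gff3(locus$genes, file.path(out, "trio_genes.gff3"))
          write_bed(locus$island, file.path(out, "islands.bed"))
        },
        clones = {
          cl <- gen_clones(gen_locus(cfg), config = cfg)
          write_fasta_seqs(cl$seqs, file.path(out, "clones.fa"))
          write_tsv(cl$truth, file.path(out, "clones_truth.tsv"))
        },
        cohort = {
          co <- gen_beta_cohort(cfg)
          write_beta_matrix(co$controls, file.path(out, "controls.tsv"))
          write_beta_matrix(co$cases, file.path(out, "cases.tsv"))
          writeLines(co$block_probes, file.path(out, "block_probes.txt"))
          write_json_report(co$truth, file.path(out, "cohort_truth.json"))
        },
        reads = write_bed(gen_reads(gen_locus(cfg), cfg),
                          file.path(out, "reads.bed")),
        annotation = {
          ann <- gen_annotation(cfg)
          write_gff3(ann$genes, file.path(out, "genes.gff3"))
          write_bed(ann$islands, file.path(out, "islands.bed"))
          write_tsv(ann$truth, file.path(out, "annotation_truth.tsv"))
        },
        variants = {
          v <- gen_variants(cfg)
          write_tsv(v$variants, file.path(out, "variants.tsv"))
          write_tsv(data.frame(sample = names(v$status),
                               status = unname(v$status)),
                    file.path(out, "status.tsv"))
          write_json_report(v$truth, file.path(out, "variants_truth.json"))
        },
        stop("unknown simulate target: ", what))
    },
    epigram = {
      ref_seq <- read_fasta_seqs(need("ref"))[[1]]
      alleles <- strsplit(need("snp-alleles"), ",")[[1]]
      ref <- build_reference(ref_seq,
                             snp_offset = as.integer(need("snp-offset")),
                             snp_alleles = alleles)
      seqs <- read_clones(need("clones"))
      calls <- Map(function(s, id) call_clone(s, ref, clone_id = id),
                   seqs, names(seqs))
      ep <- assemble_epigram(unname(calls), ref)
      write_epigram(ep, file.path(need("out"), "epigram.tsv"))
      write_json_report(call_monoallelic_epimutation(ep),
                        file.path(opts$out, "epimutation_call.json"))
    },
    mvp = {
      res <- mvp_scan(read_beta_matrix(need("cases")),
                      read_beta_matrix(need("controls")),
                      delta_threshold =
                        as.numeric(if (is.null(opts$delta)) 0.3
                                   else opts$delta))
      write_tsv(res, file.path(need("out"), "mvp.tsv"))
    },
    carriers = {
      cohort <- read_beta_matrix(need("cohort"))
      block <- readLines(need("block"))
      rep <- detect_carriers(cohort, block[nzchar(block)])
      af <- allele_frequency(length(rep$carriers), rep$n_subjects)
      write_json_report(list(carriers = rep$carriers,
                             n_subjects = rep$n_subjects,
                             allele_frequency_estimate = af$estimate,
                             allele_frequency_upper_bound = af$upper_bound),
                        file.path(need("out"), "carriers.json"))
    },
    epild = {
      bm <- read_beta_matrix(need("cohort"))
      method <- if (is.null(opts$method)) "both" else opts$method
      profile <- adjacent_ld_profile(bm, method = method)
      write_tsv(profile, file.path(need("out"), "epild_profile.tsv"))
      blocks <- build_blocks(profile,
                             r2_min = as.numeric(
                               if (is.null(opts[["r2-min"]])) 0.8
                               else opts[["r2-min"]]))
      write_json_report(lapply(blocks, function(b)
        list(probes = b$probes, min_r2 = b$min_r2)),
        file.path(opts$out, "blocks.json"))
    },
    trioscan = {
      genes <- read_gene_models(need("genes"), "gff3")
      islands <- read_bed(need("islands"), columns = 3)
      window <- as.numeric(if (is.null(opts$window)) 1000 else opts$window)
      trios <- find_trios(genes, islands, promoter_window = window)
      write_tsv(trios, file.path(need("out"), "trios.tsv"))
      write_tsv(summarize_patterns(trios),
                file.path(opts$out, "trio_counts.tsv"))
    },
    antisense = {
      genes <- read_gene_models(need("genes"), "gff3")
      reads <- read_bed(need("reads"), columns = 6)
      islands <- read_bed(need("islands"), columns = 3)
      trios <- find_trios(genes, islands)
      if (nrow(trios) == 0L) stop("antisense stage: no trio found in genes")
      rt <- detect_readthrough(reads, trios[1, ], genes)
      cls <- classify_reads(reads, genes)
      write_tsv(cls$per_gene, file.path(need("out"), "read_counts.tsv"))
      write_json_report(unclass(rt), file.path(opts$out, "readthrough.json"))
    },
    segregate = {
      v <- read_variant_table(need("variants"))
      st <- read_status_map(need("status"))
      maf <- as.numeric(if (is.null(opts[["maf-max"]])) 0.001
                        else opts[["maf-max"]])
      seg <- cosegregate(filter_variants(v, maf_max = maf), st)
      write_tsv(seg, file.path(need("out"), "segregating.tsv"))
    },
    {
      cli_help()
      stop("unknown subcommand: ", sub)
    })
  invisible(status)
}
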