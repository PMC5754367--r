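# Deterministic generators for every input the pipeline consumes.
#
# The defaults encode the study design the analysis assumes: a 462-bp
# promoter CpG island with 32 CpG sites tagged by a G/T SNP, an 8-probe
# array block inside a hypermethylated neighbourhood, a 690+350 = 1040
# subject control cohort with one planted heterozygous carrier, a
# reverse-forward-reverse trio locus with head-to-head and tail-to-tail
# partial overlaps, and a 6-sample pedigree with one planted segregating
# splice-acceptor variant.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data module with the defaults
#' that make up the stated world (see the methods vignette for rationale).
#' The same seed always yields byte-identical artifacts; every generator
#' derives an independent sub-stream from `seed` and restores the caller's
#' RNG state.
#'
#' @param seed integer master seed.
#' @param region_len length (bp) of the assayed island/region.
#' @param n_cpg number of CpG sites planted in the island.
#' @param snp_alleles length-2 vector `(tag base, other base)`; bases must
#'   avoid `C` so the tag cannot create or destroy a CpG.
#' @param n_clones_per_allele bisulfite clones per allele.
#' @param conversion_efficiency per-cytosine bisulfite conversion
#'   probability.
#' @param base_error_rate uniform per-base sequencing error probability.
#' @param n_controls,n_cases cohort sizes (690 + 350 = 1040 controls).
#' @param n_carriers_in_controls planted heterozygous carriers among
#'   controls.
#' @param block_size number of array probes in the epimutation block.
#' @param n_probes total probes (block + hypermethylated flanks).
#' @param beta_shapes list of Beta shape pairs for the UU / PM / MM states.
#' @param n_reads,readthrough_frac,read_length stranded read simulation.
#' @param n_planted_r1f2r3,n_planted_f1r2f1,n_decoys annotation scan
#'   plants; decoys each violate exactly one trio predicate.
#' @param chrom_len optional chromosome length cap for [gen_annotation()].
#' @param n_variant_decoys decoy variants around the planted segregating
#'   splice-acceptor variant.
#' @param pedigree named status vector (`carrier` / `non_carrier`) of the
#'   sequenced samples.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       region_len = 462, n_cpg = 32,
                       snp_alleles = c("G", "T"),
                       n_clones_per_allele = 30,
                       conversion_efficiency = 0.99,
                       base_error_rate = 0,
                       n_controls = 1040, n_cases = 3,
                       n_carriers_in_controls = 1,
                       block_size = 8, n_probes = 100,
                       beta_shapes = list(UU = c(2, 18), PM = c(25, 25),
                                          MM = c(18, 2)),
                       n_reads = 10000, readthrough_frac = 0,
                       read_length = 80,
                       n_planted_r1f2r3 = 50, n_planted_f1r2f1 = 10,
                       n_decoys = 500, chrom_len = NULL,
                       n_variant_decoys = 100,
                       pedigree = c(S1 = "carrier", S2 = "carrier",
                                    S3 = "carrier", S4 = "non_carrier",
                                    S5 = "non_carrier", S6 = "non_carrier")) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_cpg >= 0, cfg$region_len > 60 + 2 * max(cfg$n_cpg, 1),
            cfg$conversion_efficiency >= 0, cfg$conversion_efficiency <= 1,
            cfg$block_size <= cfg$n_probes,
            cfg$readthrough_frac >= 0, cfg$readthrough_frac <= 1)
  if (any(toupper(cfg$snp_alleles) == "C"))
    stop("snp alleles must avoid C (tag must be methylation-neutral)")
  class(cfg) <- "sim_config"
  cfg
}

# filler DNA with no CpG dinucleotide: never emit G right after C
random_noncpg_filler <- function(n) {
  out <- character(n)
  prev <- ""
  bases <- c("A", "C", "G", "T")
  draws <- sample(bases, n, replace = TRUE)
  alt <- sample(c("A", "C", "T"), n, replace = TRUE)
  for (i in seq_len(n)) {
    b <- draws[i]
    if (prev == "C" && b == "G") b <- alt[i]
    out[i] <- b
    prev <- b
  }
  out
}

#' Generate the trio locus
#'
#' Builds a synthetic chromosome `chrS` carrying a reverse (`R1`) - forward
#' (`F2`) - reverse (`R3`) gene trio with head-to-head (`R1`/`F2`) and
#' tail-to-tail (`F2`/`R3`) partial overlaps, a CpG island spanning the
#' bidirectional promoter with exactly `n_cpg` CpG sites, a
#' methylation-neutral tagging SNP inside the island, and a 6-exon `R3`
#' (so splice-acceptor consequence prediction is exercised on the terminal
#' exon).
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_locus`: `chrom`, `genes` (list of three
#'   [gene_model()]s), `island` ([genomic_intervals()] row), `region_start`,
#'   `snp_offset`, `ref` (a [build_reference()]), `truth`.
#' @export
gen_locus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  region_start <- 1050
  L <- config$region_len
  n_cpg <- config$n_cpg
  seq_chars <- with_rng_seed(derive_seed(config$seed, "locus"), {
    ch <- random_noncpg_filler(L)
    if (n_cpg > 0) {
      pos <- floor(40 + (L - 60) * (seq_len(n_cpg) - 1) / n_cpg)
      if (any(diff(pos) < 2)) stop("region too short for requested CpG count")
      for (p in pos) {
        ch[p + 1] <- "C"
        ch[p + 2] <- "G"
      }
    }
    snp <- 20
    allele <- toupper(config$snp_alleles[1])
    if (ch[snp] == "C") ch[snp] <- "A"      # no CpG from C+allele G
    ch[snp + 1] <- allele
    if (allele == "G" && ch[snp] == "C") ch[snp] <- "A"
    ch
  })
  seq <- paste(seq_chars, collapse = "")
  island <- genomic_intervals("chrS", region_start, region_start + L,
                              "+", name = "island_1")
  genes <- list(
    gene_model("R1", "chrS", 200, 1200, "-",
               exons = data.frame(start = c(200, 900), end = c(700, 1200))),
    gene_model("F2", "chrS", 1100, 4100, "+",
               exons = data.frame(start = c(1100, 2000, 3600),
                                  end = c(1500, 2500, 4100))),
    gene_model("R3", "chrS", 3900, 5300, "-",
               exons = data.frame(
                 start = c(3900, 4150, 4400, 4620, 4840, 5060),
                 end = c(4050, 4300, 4520, 4740, 4960, 5300))))
  ref <- build_reference(seq, region = island, snp_offset = 20,
                         snp_alleles = toupper(config$snp_alleles))
  if (length(ref$cpg_positions) != n_cpg)
    stop("internal error: planted ", n_cpg, " CpGs but reference has ",
         length(ref$cpg_positions))
  structure(list(chrom = "chrS", genes = genes, island = island,
                 region_start = region_start, snp_offset = 20, ref = ref,
                 truth = list(n_cpg = n_cpg,
                              snp_alleles = toupper(config$snp_alleles))),
            class = "sim_locus")
}

#' Generate bisulfite clone sequences
#'
#' Draws `n_clones_per_allele` clones per allele. Each clone carries its
#' allele's base at the SNP offset; methylated CpGs emit `C` and
#' unmethylated ones `T` according to the per-allele per-CpG methylation
#' probabilities; every non-CpG cytosine converts to `T` with probability
#' `conversion_efficiency`; optional uniform base errors follow.
#'
#' @param locus a [gen_locus()] result.
#' @param allele_states 2 x n_cpg matrix of methylation probabilities with
#'   rows `tag`, `other`; default plants a fully methylated tag allele over
#'   an unmethylated other allele (the mono-allelic epimutation).
#' @param config a [sim_config()].
#' @return List with `seqs` (named character vector, FASTA-ready) and
#'   `truth` (data frame `clone_id`, `allele`).
#' @export
gen_clones <- function(locus, allele_states = NULL, config = sim_config()) {
  stopifnot(inherits(locus, "sim_locus"))
  ref <- locus$ref
  n_cpg <- length(ref$cpg_positions)
  if (is.null(allele_states))
    allele_states <- rbind(tag = rep(1, n_cpg), other = rep(0, n_cpg))
  stopifnot(nrow(allele_states) == 2L, ncol(allele_states) == n_cpg)
  ref_chars <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  n <- config$n_clones_per_allele
  with_rng_seed(derive_seed(config$seed, "clones"), {
    seqs <- character(2 * n)
    ids <- character(2 * n)
    alleles <- character(2 * n)
    k <- 0L
    for (a in c("tag", "other")) {
      base <- if (a == "tag") ref$snp_alleles[1] else ref$snp_alleles[2]
      for (i in seq_len(n)) {
        k <- k + 1L
        ch <- ref_chars
        ch[ref$snp_offset + 1L] <- base
        if (n_cpg > 0) {
          meth <- stats::rbinom(n_cpg, 1L, allele_states[a, ]) == 1L
          ch[ref$cpg_positions + 1L] <- ifelse(meth, "C", "T")
        }
        conv <- stats::rbinom(length(ref$noncpg_c_positions), 1L,
                              config$conversion_efficiency) == 1L
        ch[ref$noncpg_c_positions + 1L] <- ifelse(conv, "T", "C")
        if (config$base_error_rate > 0) {
          hit <- which(stats::runif(length(ch)) < config$base_error_rate)
          for (p in hit)
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        }
        ids[k] <- sprintf("clone_%s_%03d", a, i)
        alleles[k] <- a
        seqs[k] <- paste(ch, collapse = "")
      }
    }
    list(seqs = stats::setNames(seqs, ids),
         truth = data.frame(clone_id = ids, allele = alleles,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a methylation-array cohort
#'
#' Controls carry an unmethylated (`UU`-distributed) block of
#' `block_size` probes surrounded by hypermethylated (`MM`) flanking
#' probes; the planted heterozygous carriers (and every case) draw the
#' block from the intermediate `PM` distribution instead.
#'
#' @param config a [sim_config()].
#' @return List with `controls` and `cases` ([beta_matrix()]),
#'   `block_probes` (probe ids) and `truth` (`control_carriers`,
#'   `case_ids`).
#' @export
gen_beta_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  nb <- config$block_size
  nf <- config$n_probes - nb
  n_left <- ceiling(nf / 2)
  n_right <- nf - n_left
  pos <- c(if (n_left) 500 * seq_len(n_left),
           30000 + 50 * seq_len(nb),
           if (n_right) 40000 + 500 * seq_len(n_right))
  probes <- data.frame(probe_id = sprintf("cg%05d", seq_along(pos)),
                       chrom = "chrS", pos = pos, stringsAsFactors = FALSE)
  block_ids <- probes$probe_id[n_left + seq_len(nb)]
  sh <- config$beta_shapes
  with_rng_seed(derive_seed(config$seed, "cohort"), {
    nC <- config$n_controls
    carriers <- sort(sample(nC, config$n_carriers_in_controls))
    ctrl_ids <- sprintf("ctrl_%04d", seq_len(nC))
    vals <- matrix(NA_real_, nC, length(pos))
    flank <- c(seq_len(n_left), n_left + nb + seq_len(n_right))
    vals[, flank] <- stats::rbeta(nC * nf, sh$MM[1], sh$MM[2])
    block_cols <- n_left + seq_len(nb)
    vals[, block_cols] <- stats::rbeta(nC * nb, sh$UU[1], sh$UU[2])
    for (s in carriers)
      vals[s, block_cols] <- stats::rbeta(nb, sh$PM[1], sh$PM[2])
    controls <- beta_matrix(probes, vals, ctrl_ids)
    nCa <- config$n_cases
    case_ids <- sprintf("case_%02d", seq_len(nCa))
    cvals <- matrix(NA_real_, nCa, length(pos))
    cvals[, flank] <- stats::rbeta(nCa * nf, sh$MM[1], sh$MM[2])
    cvals[, block_cols] <- stats::rbeta(nCa * nb, sh$PM[1], sh$PM[2])
    cases <- beta_matrix(probes, cvals, case_ids)
    list(controls = controls, cases = cases, block_probes = block_ids,
         truth = list(control_carriers = ctrl_ids[carriers],
                      case_ids = case_ids))
  })
}

#' Generate unphased epigenotype pairs from phase-known epihaplotypes
#'
#' Draws `2n` epihaplotypes from the given UU/UM/MU/MM frequencies and
#' pairs them at random (no Hardy-Weinberg departure), returning the
#' unphased dosages at the two loci. Used to compare the EM and composite
#' estimators under their shared model.
#'
#' @param n number of subjects.
#' @param hap_freqs numeric length-4 vector (UU, UM, MU, MM), summing to 1.
#' @param seed RNG seed.
#' @return List with integer vectors `g1`, `g2`.
#' @export
gen_epigenotypes <- function(n, hap_freqs, seed = 1) {
  stopifnot(length(hap_freqs) == 4L, abs(sum(hap_freqs) - 1) < 1e-9)
  with_rng_seed(seed, {
    hap <- sample(4L, 2 * n, replace = TRUE, prob = hap_freqs)
    a1 <- c(0L, 0L, 1L, 1L)[hap]  # allele at locus 1 per haplotype
    a2 <- c(0L, 1L, 0L, 1L)[hap]
    i <- seq_len(n)
    list(g1 = a1[2 * i - 1] + a1[2 * i], g2 = a2[2 * i - 1] + a2[2 * i])
  })
}

#' Generate stranded reads with optional antisense readthrough
#'
#' A fraction `1 - readthrough_frac` of reads is drawn sense over the three
#' trio gene bodies (uniform placement); `readthrough_frac` is drawn on the
#' `R3` strand tiling uniformly from the middle of the `R3` body across the
#' tail-to-tail junction through `F2` into the first (transcription-order)
#' exon region of `R1`.
#'
#' @param locus a [gen_locus()] result.
#' @param config a [sim_config()].
#' @return A [genomic_intervals()] of BED6-ready reads.
#' @export
gen_reads <- function(locus, config = sim_config()) {
  stopifnot(inherits(locus, "sim_locus"))
  L <- config$read_length
  genes <- locus$genes
  n_rt <- round(config$readthrough_frac * config$n_reads)
  n_sense <- config$n_reads - n_rt
  if (config$n_reads == 0)
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  with_rng_seed(derive_seed(config$seed, "reads"), {
    per <- rep(n_sense %/% length(genes), length(genes))
    per[1] <- per[1] + n_sense %% length(genes)
    chrom <- character(0); start <- numeric(0); strand <- character(0)
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      if (per[gi] == 0) next
      lo <- g$start
      hi <- max(g$start + 1, g$end - L)
      start <- c(start, floor(stats::runif(per[gi], lo, hi)))
      strand <- c(strand, rep(g$strand, per[gi]))
    }
    if (n_rt > 0) {
      r1 <- genes[[1]]; r3 <- genes[[3]]
      span_lo <- r1$exons$start[nrow(r1$exons)]  # R1 first exon (txn order)
      span_hi <- floor((r3$start + r3$end) / 2) - L
      start <- c(start, floor(stats::runif(n_rt, span_lo, span_hi)))
      strand <- c(strand, rep(r3$strand, n_rt))
    }
    genomic_intervals(locus$chrom, start, start + L, strand,
                      name = sprintf("read_%06d", seq_along(start)),
                      score = 0)
  })
}

# slab templates for gen_annotation; offsets within one slab
annotation_unit <- function(kind, prefix, offset) {
  g <- function(id, s, e, strand, exons = NULL)
    gene_model(paste0(prefix, "_", id), "chrS", offset + s, offset + e,
               strand, exons = if (is.null(exons)) NULL else
                 data.frame(start = offset + exons$start,
                            end = offset + exons$end))
  island <- NULL
  if (kind == "R1F2R3" || kind == "decoy_no_overlap" ||
      kind == "decoy_same_strand") {
    genes <- list(
      g("R1", 200, 1200, if (kind == "decoy_same_strand") "+" else "-"),
      g("F2", 1100, 4100, "+"),
      if (kind == "decoy_no_overlap") g("R3", 4200, 5600, "-")
      else g("R3", 3900, 5300, "-"))
    island <- c(offset + 1050, offset + 1512)
  } else if (kind == "decoy_no_island") {
    genes <- list(g("R1", 200, 1200, "-"), g("F2", 1100, 4100, "+"),
                  g("R3", 3900, 5300, "-"))
  } else if (kind == "F1R2F1") {
    genes <- list(g("F1a", 200, 1400, "+"), g("R2", 1100, 4100, "-"),
                  g("F1b", 4000, 5300, "+"))
    island <- c(offset + 3950, offset + 4200)
  } else stop("unknown unit kind: ", kind)
  list(genes = genes, island = island, kind = kind)
}

#' Generate a planted-trio gene annotation
#'
#' Plants `n_planted_r1f2r3` + `n_planted_f1r2f1` trios that satisfy every
#' trio predicate, plus `n_decoys` decoy gene groups each violating exactly
#' one predicate (same-strand flank, missing island, or no 3' overlap,
#' cycled uniformly). Units are placed on non-interacting 20-kb slabs of a
#' synthetic chromosome with a small jittered offset.
#'
#' @param config a [sim_config()].
#' @return List with `genes` (list of [gene_model()]), `islands`
#'   ([genomic_intervals()]) and `truth` (data frame of planted trios:
#'   `pattern`, `gene1`, `gene2`, `gene3`).
#' @export
gen_annotation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  kinds <- c(rep("R1F2R3", config$n_planted_r1f2r3),
             rep("F1R2F1", config$n_planted_f1r2f1),
             rep(c("decoy_same_strand", "decoy_no_island",
                   "decoy_no_overlap"),
                 length.out = config$n_decoys))
  stride <- 20000
  needed <- (length(kinds) + 1) * stride
  if (!is.null(config$chrom_len) && config$chrom_len < needed)
    stop("chromosome too short for requested gene units (need ", needed,
         " bp)")
  with_rng_seed(derive_seed(config$seed, "annotation"), {
    jitter <- sample(0:200, length(kinds), replace = TRUE)
    genes <- list()
    isl_start <- numeric(0); isl_end <- numeric(0)
    truth <- data.frame(pattern = character(), gene1 = character(),
                        gene2 = character(), gene3 = character(),
                        stringsAsFactors = FALSE)
    for (i in seq_along(kinds)) {
      prefix <- if (grepl("^decoy", kinds[i])) sprintf("d%04d", i)
                else sprintf("t%04d", i)
      unit <- annotation_unit(kinds[i], prefix, (i - 1) * stride + jitter[i])
      genes <- c(genes, unit$genes)
      if (!is.null(unit$island)) {
        isl_start <- c(isl_start, unit$island[1])
        isl_end <- c(isl_end, unit$island[2])
      }
      if (kinds[i] %in% c("R1F2R3", "F1R2F1")) {
        ids <- vapply(unit$genes, `[[`, "", "gene_id")
        truth <- rbind(truth, data.frame(
          pattern = kinds[i], gene1 = ids[1], gene2 = ids[2],
          gene3 = ids[3], stringsAsFactors = FALSE))
      }
    }
    islands <- if (length(isl_start))
      genomic_intervals("chrS", isl_start, isl_end, "+",
                        name = sprintf("isl_%04d", seq_along(isl_start)))
    else genomic_intervals(character(), numeric(), numeric())[0, ]
    list(genes = genes, islands = islands, truth = truth)
  })
}

#' Generate a pedigree variant table with one planted segregating variant
#'
#' Plants a rare splice-acceptor variant that is `het` in every epimutation
#' carrier and `hom_ref` in every non-carrier, among decoys that each
#' violate exactly one of: rarity (common MAF), damage class (benign), or
#' the segregation pattern (cycled).
#'
#' @param config a [sim_config()].
#' @return List with `variants` (data frame, [read_variant_table()] shape),
#'   `status` (named vector) and `truth` (`key` of the planted variant as
#'   `chrom:pos:ref:alt`).
#' @export
gen_variants <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  status <- config$pedigree
  if (sum(status == "carrier") < 1 || sum(status == "non_carrier") < 1)
    stop("pedigree must contain at least one carrier and one non-carrier")
  samples <- names(status)
  seg_pattern <- ifelse(status == "carrier", "het", "hom_ref")
  with_rng_seed(derive_seed(config$seed, "variants"), {
    n <- config$n_variant_decoys + 1L
    pos <- sort(sample(1e6:2e6, n))
    planted_row <- sample(n, 1)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    consequence <- character(n)
    maf <- numeric(n)
    gts <- matrix("", n, length(samples), dimnames = list(NULL, samples))
    decoy_kind <- rep_len(c("common", "benign", "non_segregating"), n)
    j <- 0L
    for (i in seq_len(n)) {
      if (i == planted_row) {
        consequence[i] <- "splice_site"
        maf[i] <- 5e-4
        gts[i, ] <- seg_pattern
        next
      }
      j <- j + 1L
      kind <- decoy_kind[j]
      if (kind == "common") {
        consequence[i] <- sample(DAMAGE_CLASSES, 1)
        maf[i] <- stats::runif(1, 0.002, 0.05)
        gts[i, ] <- seg_pattern
      } else if (kind == "benign") {
        consequence[i] <- "other"
        maf[i] <- stats::runif(1, 0, 0.001)
        gts[i, ] <- seg_pattern
      } else {
        consequence[i] <- sample(DAMAGE_CLASSES, 1)
        maf[i] <- stats::runif(1, 0, 0.001)
        g <- seg_pattern
        breakage <- sample(c("het_noncarrier", "ref_carrier", "missing",
                             "hom_alt_carrier"), 1)
        carr <- which(status == "carrier")
        nonc <- which(status == "non_carrier")
        if (breakage == "het_noncarrier") g[sample(nonc, 1)] <- "het"
        else if (breakage == "ref_carrier") g[sample(carr, 1)] <- "hom_ref"
        else if (breakage == "missing") g[sample(seq_along(g), 1)] <- "missing"
        else g[sample(carr, 1)] <- "hom_alt"
        gts[i, ] <- g
      }
    }
    variants <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                           consequence = consequence, max_maf = maf,
                           stringsAsFactors = FALSE)
    for (s in samples) variants[[s]] <- gts[, s]
    attr(variants, "samples") <- samples
    key <- sprintf("chr1:%d:%s:%s", pos[planted_row], ref[planted_row],
                   alt[planted_row])
    list(variants = variants, status = status, truth = list(key = key))
  })
}
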