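test_that("gen_locus plants the island CpGs, SNP and trio geometry", {
  cfg <- sim_config(seed = 3)
  locus <- gen_locus(cfg)
  expect_length(locus$ref$cpg_positions, 32L)
  expect_gt(length(locus$ref$noncpg_c_positions), 20L)
  # the trio genes satisfy the scan predicates with the island
  trios <- find_trios(locus$genes, locus$island)
  expect_equal(trios$pattern, "R1F2R3")
  # determinism: same seed, byte-identical sequence
  expect_identical(gen_locus(cfg)$ref$seq, locus$ref$seq)
  expect_false(identical(gen_locus(sim_config(seed = 4))$ref$seq,
                         locus$ref$seq))
  # degenerate: no CpGs
  l0 <- gen_locus(sim_config(seed = 3, n_cpg = 0))
  expect_length(l0$ref$cpg_positions, 0L)
})

test_that("gen_clones emits tagged clones whose QC follows the binomial tail", {
  cfg <- sim_config(seed = 5, n_clones_per_allele = 30)
  locus <- gen_locus(cfg)
  cl <- gen_clones(locus, config = cfg)
  expect_length(cl$seqs, 60L)
  expect_identical(gen_clones(locus, config = cfg)$seqs, cl$seqs)
  # perfect conversion forces rate 1.0 on every clone
  cfgp <- sim_config(seed = 5, conversion_efficiency = 1.0)
  clp <- gen_clones(locus, config = cfgp)
  rates <- vapply(names(clp$seqs), function(id)
    call_clone(clp$seqs[[id]], locus$ref, id)$conversion_rate, 0)
  expect_true(all(rates == 1.0))
  # QC pass rate at conversion 0.90 matches the exact binomial tail:
  # pass iff Binomial(m, 0.90) > 0.95 m, m = number of non-CpG cytosines
  cfg90 <- sim_config(seed = 6, conversion_efficiency = 0.90,
                      n_clones_per_allele = 500)
  cl90 <- gen_clones(locus, config = cfg90)
  pass <- vapply(names(cl90$seqs), function(id)
    call_clone(cl90$seqs[[id]], locus$ref, id)$passed_qc, logical(1))
  m <- length(locus$ref$noncpg_c_positions)
  k_min <- floor(0.95 * m) + 1  # smallest count with k/m > 0.95
  p_exact <- sum(dbinom(k_min:m, m, 0.90))
  mc_se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(mean(pass) - p_exact), 4 * mc_se + 1e-6)
})

test_that("gen_beta_cohort plants carriers recoverable by detect_carriers", {
  cfg <- sim_config(seed = 9, n_controls = 300)
  co <- gen_beta_cohort(cfg)
  expect_equal(dim(co$controls$values), c(300L, 100L))
  expect_length(co$block_probes, 8L)
  rep <- detect_carriers(co$controls, co$block_probes)
  expect_equal(rep$carriers, co$truth$control_carriers)
  # zero planted carriers -> zero found
  co0 <- gen_beta_cohort(sim_config(seed = 9, n_controls = 300,
                                    n_carriers_in_controls = 0))
  expect_length(detect_carriers(co0$controls, co0$block_probes)$carriers, 0L)
  # determinism at the value level
  co2 <- gen_beta_cohort(cfg)
  expect_identical(co2$controls$values, co$controls$values)
  # and at the byte level through the TSV writer
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_beta_matrix(co$controls, f1)
  write_beta_matrix(co2$controls, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("gen_annotation plants trios and one-violation decoys", {
  cfg <- sim_config(seed = 21, n_planted_r1f2r3 = 4, n_planted_f1r2f1 = 2,
                    n_decoys = 9)
  ann <- gen_annotation(cfg)
  expect_length(ann$genes, 3L * 15L)
  trios <- find_trios(ann$genes, ann$islands)
  counts <- summarize_patterns(trios)
  expect_equal(counts$n, c(4L, 2L))
  called <- sort(paste(trios$gene1, trios$gene2, trios$gene3))
  planted <- sort(paste(ann$truth$gene1, ann$truth$gene2, ann$truth$gene3))
  expect_equal(called, planted)
  # zero planted -> zero called
  ann0 <- gen_annotation(sim_config(seed = 21, n_planted_r1f2r3 = 0,
                                    n_planted_f1r2f1 = 0, n_decoys = 12))
  expect_equal(nrow(find_trios(ann0$genes, ann0$islands)), 0L)
  # chromosome length cap
  expect_error(gen_annotation(sim_config(seed = 1, chrom_len = 1e4)),
               "too short")
  # determinism through the GFF3 writer
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gff3(ann$genes, f1)
  write_gff3(gen_annotation(cfg)$genes, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("gen_reads covers gene bodies and is empty at n_reads = 0", {
  cfg <- sim_config(seed = 2, n_reads = 600, readthrough_frac = 0)
  locus <- gen_locus(cfg)
  reads <- gen_reads(locus, cfg)
  expect_equal(nrow(reads), 600L)
  cls <- classify_reads(reads, locus$genes)
  expect_true(all(cls$per_gene$sense > 0))
  expect_equal(nrow(gen_reads(locus, sim_config(seed = 2, n_reads = 0))), 0L)
  expect_identical(gen_reads(locus, cfg), reads)
})

test_that("gen_variants plants one segregating variant among decoys", {
  cfg <- sim_config(seed = 13, n_variant_decoys = 40)
  v <- gen_variants(cfg)
  expect_equal(nrow(v$variants), 41L)
  seg <- cosegregate(filter_variants(v$variants), v$status)
  expect_equal(nrow(seg), 1L)
  expect_equal(sprintf("chr1:%d:%s:%s", seg$pos, seg$ref, seg$alt),
               v$truth$key)
  expect_identical(gen_variants(cfg)$variants, v$variants)
  expect_error(gen_variants(sim_config(
    seed = 1, pedigree = c(A = "carrier", B = "carrier"))),
    "non-carrier")
})

test_that("gen_epigenotypes reproduces the requested haplotype frequencies", {
  hf <- c(0.4, 0.1, 0.2, 0.3)
  d <- gen_epigenotypes(20000, hf, seed = 8)
  # allele frequencies: pA = f(MU) + f(MM), pB = f(UM) + f(MM)
  expect_equal(mean(d$g1) / 2, hf[3] + hf[4], tolerance = 0.02)
  expect_equal(mean(d$g2) / 2, hf[2] + hf[4], tolerance = 0.02)
  expect_identical(gen_epigenotypes(100, hf, seed = 8),
                   gen_epigenotypes(100, hf, seed = 8))
})
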