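test_that("tail-to-tail geometry: partial 3' overlap only", {
  mk <- function(id, s, e, str) gene_model(id, "chr1", s, e, str)
  # overlap containing both 3' ends
  tt <- find_tail_to_tail(list(mk("P", 100, 600, "+"), mk("M", 500, 900, "-")))
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$overlap_start, 500)
  expect_equal(tt$overlap_end, 600)
  # disjoint genes are not a pair
  expect_equal(nrow(find_tail_to_tail(list(mk("P", 100, 600, "+"),
                                           mk("M", 700, 900, "-")))), 0L)
  # containment is excluded (M's 5' end also inside P)
  expect_equal(nrow(find_tail_to_tail(list(mk("P", 100, 900, "+"),
                                           mk("M", 200, 600, "-")))), 0L)
  # same strand never pairs
  expect_equal(nrow(find_tail_to_tail(list(mk("A", 100, 600, "+"),
                                           mk("B", 500, 900, "+")))), 0L)
})

test_that("head-to-head geometry: 5' overlap or proximal divergence", {
  mk <- function(id, s, e, str) gene_model(id, "chr1", s, e, str)
  hh <- find_head_to_head(list(mk("M", 100, 550, "-"),
                               mk("P", 500, 2000, "+")))
  expect_equal(nrow(hh), 1L)
  expect_equal(hh$geometry, "head_to_head")
  expect_equal(c(hh$overlap_start, hh$overlap_end), c(500, 550))
  # divergent non-overlapping within the promoter window
  hh <- find_head_to_head(list(mk("M", 100, 400, "-"),
                               mk("P", 600, 2000, "+")),
                          promoter_window = 1000)
  expect_equal(hh$geometry, "head_to_head_proximal")
  expect_equal(hh$gap, 200)
  # outside the window: no pair
  expect_equal(nrow(find_head_to_head(list(mk("M", 100, 400, "-"),
                                           mk("P", 1600, 2000, "+")),
                                      promoter_window = 1000)), 0L)
})

test_that("pair predicates are translation-invariant and order-symmetric", {
  mk <- function(id, s, e, str, off = 0) gene_model(id, "chr1", s + off,
                                                    e + off, str)
  for (off in c(0, 12345)) {
    g <- list(mk("P", 100, 600, "+", off), mk("M", 500, 900, "-", off))
    expect_equal(nrow(find_tail_to_tail(g)), 1L)
    expect_equal(nrow(find_tail_to_tail(rev(g))), 1L)
  }
})

test_that("find_trios requires all three predicates", {
  genes <- toy_trio_genes()  # R1(-,100-550) F2(+,500-2000) R3(-,1900-3000)
  island <- genomic_intervals("chr1", 450, 700, "+")
  trios <- find_trios(genes, island)
  expect_equal(nrow(trios), 1L)
  expect_equal(trios$pattern, "R1F2R3")
  expect_equal(c(trios$gene1, trios$gene2, trios$gene3), c("R1", "F2", "R3"))
  # no island -> no trio
  far <- genomic_intervals("chr1", 9000, 9100, "+")
  expect_equal(nrow(find_trios(genes, far)), 0L)
  # R1 on the wrong strand -> no trio
  genes2 <- genes
  genes2[[1]] <- gene_model("R1", "chr1", 100, 550, "+")
  expect_equal(nrow(find_trios(genes2, island)), 0L)
})

test_that("strand-mirroring maps R1F2R3 onto F1R2F1 one-to-one", {
  genes <- toy_trio_genes()
  island <- genomic_intervals("chr1", 450, 700, "+")
  L <- 5000  # mirror coordinates within a 5-kb frame and flip strands
  mirror_gene <- function(g) gene_model(g$gene_id, g$chrom, L - g$end,
                                        L - g$start,
                                        if (g$strand == "+") "-" else "+")
  mgenes <- lapply(genes, mirror_gene)
  misland <- genomic_intervals("chr1", L - island$end, L - island$start, "+")
  trios <- find_trios(mgenes, misland)
  expect_equal(nrow(trios), 1L)
  expect_equal(trios$pattern, "F1R2F1")
  # genomic order reverses under mirroring
  expect_equal(c(trios$gene1, trios$gene2, trios$gene3), c("R3", "F2", "R1"))
})

test_that("summarize_patterns counts and duplicate genes are deduplicated", {
  genes <- toy_trio_genes()
  island <- genomic_intervals("chr1", 450, 700, "+")
  trios <- find_trios(genes, island)
  counts <- summarize_patterns(trios)
  expect_equal(counts$n[counts$pattern == "R1F2R3"], 1L)
  expect_equal(counts$n[counts$pattern == "F1R2F1"], 0L)
  expect_equal(summarize_patterns(trios[0, ])$n, c(0L, 0L))
  expect_warning(find_trios(c(genes, genes[1]), island), "duplicate")
})
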