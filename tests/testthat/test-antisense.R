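test_that("classify_reads assigns sense/antisense/intergenic", {
  genes <- toy_trio_genes()
  reads <- genomic_intervals("chr1",
                             c(600, 700, 5000, 120),
                             c(680, 780, 5080, 200),
                             c("+", "-", "+", "-"))
  cls <- classify_reads(reads, genes)
  f2 <- cls$per_gene[cls$per_gene$gene_id == "F2", ]
  expect_equal(f2$sense, 1L)       # read(+) over F2(+)
  expect_equal(f2$antisense, 1L)   # read(-) over F2(+)
  r1 <- cls$per_gene[cls$per_gene$gene_id == "R1", ]
  expect_equal(r1$sense, 1L)       # read(-) over R1(-)
  expect_equal(cls$intergenic, 1L)
  # totals: sense + antisense + intergenic = reads + multiplicities
  expect_equal(sum(cls$per_gene$sense) + sum(cls$per_gene$antisense) +
                 cls$intergenic, nrow(reads) + cls$multi)
  # reverse orientation flips every call
  cls_r <- classify_reads(reads, genes, orientation = "reverse")
  expect_equal(cls_r$per_gene$sense, cls$per_gene$antisense)
})

tile_reads <- function(from, to, strand, len = 50, by = 10) {
  s <- seq(from, to - len, by = by)
  genomic_intervals("chr1", s, s + len, strand)
}

test_that("detect_readthrough requires contiguity, fraction and ratio", {
  genes <- toy_trio_genes()
  island <- genomic_intervals("chr1", 450, 700, "+")
  trio <- find_trios(genes, island)[1, ]
  sense_f2 <- tile_reads(500, 2000, "+")
  # dense antisense tiling from inside R3 through all of F2
  rt <- tile_reads(520, 2500, "-")
  call <- detect_readthrough(rbind(sense_f2, rt), trio, genes,
                             min_depth = 2, min_ratio = 0.5)
  expect_true(call$is_readthrough)
  expect_true(call$contiguous_with_r3)
  expect_gt(call$antisense_fraction_f2, 0.9)
  # no antisense reads at all: fraction 0, false
  call0 <- detect_readthrough(sense_f2, trio, genes)
  expect_false(call0$is_readthrough)
  expect_equal(call0$antisense_fraction_f2, 0)
  # antisense over F2 but nothing over R3: no contiguity -> false
  mid_only <- tile_reads(600, 1800, "-")
  call1 <- detect_readthrough(rbind(sense_f2, mid_only), trio, genes,
                              min_depth = 2, min_ratio = 0.5)
  expect_false(call1$contiguous_with_r3)
  expect_false(call1$is_readthrough)
})

test_that("detect_readthrough is monotone in its thresholds", {
  genes <- toy_trio_genes()
  island <- genomic_intervals("chr1", 450, 700, "+")
  trio <- find_trios(genes, island)[1, ]
  reads <- rbind(tile_reads(500, 2000, "+", by = 40),
                 tile_reads(520, 2500, "-", by = 20))
  base <- detect_readthrough(reads, trio, genes, min_depth = 2,
                             min_fraction = 0.5, min_ratio = 0.5)
  for (depth in c(2, 5, 50, 500)) {
    for (fr in c(0.5, 0.9, 1)) {
      call <- detect_readthrough(reads, trio, genes, min_depth = depth,
                                 min_fraction = fr, min_ratio = 0.5)
      if (call$is_readthrough) expect_true(base$is_readthrough)
    }
  }
})

test_that("acceptor_disruption is strand-aware with mirrored intron indices", {
  # minus-strand 6-exon gene: exon 6 (transcription) is the leftmost
  starts <- c(100, 300, 500, 700, 900, 1100)
  ends <- starts + 100
  gm <- gene_model("R3", "chr1", 100, 1200, "-",
                   exons = data.frame(start = starts, end = ends))
  # acceptor -1 of intron 5 = first intronic base right of exon 1 (genomic)
  hit <- acceptor_disruption(gm, 200)
  expect_equal(hit$hit, "acceptor_minus1")
  expect_equal(hit$intron_index, 5L)
  expect_equal(hit$predicted, "terminal_exon_skipped_polyA_lost")
  hit2 <- acceptor_disruption(gm, 201)
  expect_equal(hit2$hit, "acceptor_minus2")
  expect_equal(hit2$predicted, "terminal_exon_skipped_polyA_lost")
  # -3 is outside the canonical site
  expect_equal(acceptor_disruption(gm, 202)$hit, "none")
  # internal acceptor (intron 1, before exon 2 in transcription order)
  internal <- acceptor_disruption(gm, 1000)
  expect_equal(internal$intron_index, 1L)
  expect_equal(internal$predicted, "internal_exon_skipped")
  # plus-strand mirror of the same exon structure
  gp <- gene_model("F", "chr1", 100, 1200, "+",
                   exons = data.frame(start = starts, end = ends))
  hp <- acceptor_disruption(gp, starts[6] - 1)
  expect_equal(hp$hit, "acceptor_minus1")
  expect_equal(hp$intron_index, 5L)
  expect_equal(hp$predicted, "terminal_exon_skipped_polyA_lost")
  hp1 <- acceptor_disruption(gp, starts[2] - 1)
  expect_equal(hp1$intron_index, 1L)
  expect_equal(hp1$predicted, "internal_exon_skipped")
  # outside the gene span
  out <- acceptor_disruption(gm, 5000)
  expect_equal(out$predicted, "none")
  expect_match(out$note, "outside")
  expect_error(acceptor_disruption(gene_model("x", "chr1", 1, 10, "+"), 5),
               "at least 2 exons")
})
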