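# shared fixture builders (all fixtures are built in code)

# beta_matrix from a subjects x probes matrix, probes placed consecutively
quick_bm <- function(values, chrom = "chr1", pos = NULL,
                     subjects = NULL, probe_ids = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(values)) * 100
  if (is.null(subjects)) subjects <- sprintf("s%03d", seq_len(nrow(values)))
  if (is.null(probe_ids)) probe_ids <- sprintf("p%03d", seq_len(ncol(values)))
  beta_matrix(data.frame(probe_id = probe_ids, chrom = chrom, pos = pos,
                         stringsAsFactors = FALSE),
              values, subjects)
}

# dosage vectors from genotype-pair counts, e.g. c("0,0" = 30, "1,1" = 40)
dosages_from_counts <- function(counts) {
  g1 <- integer(0); g2 <- integer(0)
  for (k in names(counts)) {
    ij <- as.integer(strsplit(k, ",")[[1]])
    g1 <- c(g1, rep(ij[1], counts[[k]]))
    g2 <- c(g2, rep(ij[2], counts[[k]]))
  }
  list(g1 = g1, g2 = g2)
}

# random unphased genotype table of n subjects from haplotype freqs
random_genotype_table <- function(n, hap_freqs) {
  hap <- sample(4L, 2 * n, replace = TRUE, prob = hap_freqs)
  a1 <- c(0L, 0L, 1L, 1L)[hap]
  a2 <- c(0L, 1L, 0L, 1L)[hap]
  i <- seq_len(n)
  list(g1 = a1[2 * i - 1] + a1[2 * i], g2 = a2[2 * i - 1] + a2[2 * i])
}

# a tiny trio locus (R1F2R3) used by trioscan/antisense unit tests
toy_trio_genes <- function() {
  list(gene_model("R1", "chr1", 100, 550, "-"),
       gene_model("F2", "chr1", 500, 2000, "+"),
       gene_model("R3", "chr1", 1900, 3000, "-"))
}
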