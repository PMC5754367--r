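# Strand-aware read classification, antisense readthrough detection and
# splice-acceptor consequence prediction.

#' Classify stranded reads against gene models
#'
#' A read overlapping a gene body counts as sense when strands match and
#' antisense otherwise; a read overlapping several genes counts toward each
#' (the extra multiplicity is reported). Reads overlapping no gene are
#' tallied as intergenic.
#'
#' @param reads [genomic_intervals()] of stranded read intervals (read
#'   strand = inferred RNA strand under the default forward protocol).
#' @param genes list of [gene_model()] objects.
#' @param orientation `"forward"` (read strand equals RNA strand) or
#'   `"reverse"` (flip read strands first).
#' @return List with `per_gene` (data frame `gene_id`, `sense`,
#'   `antisense`), `intergenic` (read count) and `multi` (number of extra
#'   gene assignments beyond one per read).
#' @export
classify_reads <- function(reads, genes, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  validate_intervals(reads)
  strand <- reads$strand
  if (orientation == "reverse")
    strand <- ifelse(strand == "+", "-", "+")
  df <- genes_df(genes)
  hits_per_read <- integer(nrow(reads))
  sense <- antisense <- integer(nrow(df))
  for (g in seq_len(nrow(df))) {
    ov <- reads$chrom == df$chrom[g] &
      reads$start < df$end[g] & reads$end > df$start[g]
    hits_per_read <- hits_per_read + ov
    sense[g] <- sum(ov & strand == df$strand[g])
    antisense[g] <- sum(ov & strand != df$strand[g])
  }
  list(per_gene = data.frame(gene_id = df$gene_id, sense = sense,
                             antisense = antisense,
                             stringsAsFactors = FALSE),
       intergenic = sum(hits_per_read == 0L),
       multi = sum(pmax(hits_per_read - 1L, 0L)))
}

# per-base depth over [span_start, span_end) for reads on one strand
strand_coverage <- function(reads, chrom, span_start, span_end, strand) {
  width <- span_end - span_start
  cov <- numeric(width)
  sel <- reads$chrom == chrom & reads$strand == strand &
    reads$start < span_end & reads$end > span_start
  if (!any(sel)) return(cov)
  s <- pmax(reads$start[sel], span_start) - span_start + 1
  e <- pmin(reads$end[sel], span_end) - span_start
  delta <- numeric(width + 1)
  for (k in seq_along(s)) {
    delta[s[k]] <- delta[s[k]] + 1
    delta[e[k] + 1] <- delta[e[k] + 1] - 1
  }
  cumsum(delta)[seq_len(width)]
}

#' Detect antisense readthrough across a gene trio
#'
#' Tests whether transcription on the strand of the downstream reverse gene
#' (`R3` in an `R1F2R3` trio) extends aberrantly through the body of the
#' middle gene (`F2`). Per-base coverage on that strand is computed over the
#' `F2`+`R3` span; the call requires (1) contiguity -- a single run of bases
#' with depth `>= min_depth` carrying at least one base inside the `R3`
#' body and one base in the `F2`-exclusive region (crossing the gene
#' junction), (2) `antisense_fraction_f2` at least `min_fraction`, and
#' (3) an antisense/sense read-count ratio over `F2` of at least
#' `min_ratio`. The mirrored `F1R2F1` geometry is handled symmetrically
#' (the flank is then `gene1`).
#'
#' `antisense_fraction_f2` is the covered fraction of the `F2`-exclusive
#' body: bases of `F2` that overlap an opposite-strand trio partner are
#' excluded from the denominator, because ordinary sense transcription of
#' the overlapping flank genes covers those bases even in a library with no
#' readthrough at all. A readthrough-free library therefore scores an
#' antisense fraction of exactly 0.
#'
#' @param reads stranded read intervals ([genomic_intervals()]).
#' @param trio one row of [find_trios()] output (or a list with `pattern`,
#'   `gene1`..`gene3`).
#' @param genes list of [gene_model()] objects containing the trio genes.
#' @param min_depth minimum per-base depth for "covered".
#' @param min_fraction minimum covered fraction of the middle gene body.
#' @param min_ratio minimum antisense/sense read-count ratio over the
#'   middle gene.
#' @param orientation library orientation, as in [classify_reads()].
#' @return Object of class `readthrough_call`: `antisense_fraction_f2`,
#'   `contiguous_with_r3`, `sense_antisense_ratio_f2`, `is_readthrough`,
#'   plus the thresholds used.
#' @export
detect_readthrough <- function(reads, trio, genes, min_depth = 5,
                               min_fraction = 0.5, min_ratio = 1.0,
                               orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  validate_intervals(reads)
  if (orientation == "reverse")
    reads$strand <- ifelse(reads$strand == "+", "-", "+")
  by_id <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  if (is.null(trio$pattern) || is.na(trio$pattern))
    stop("trio must carry a pattern (R1F2R3 or F1R2F1)")
  mid <- by_id[[as.character(trio$gene2)]]
  flank <- if (trio$pattern == "R1F2R3") by_id[[as.character(trio$gene3)]]
           else by_id[[as.character(trio$gene1)]]
  if (is.null(mid) || is.null(flank))
    stop("trio genes not found in gene list (needs middle gene and its ",
         "tail-to-tail flank)")
  as_strand <- flank$strand  # readthrough runs on the flank's strand
  span <- c(min(mid$start, flank$start), max(mid$end, flank$end))
  cov <- strand_coverage(reads, mid$chrom, span[1], span[2], as_strand)
  covered <- cov >= min_depth
  pos0 <- span[1]  # genomic coordinate of cov[1]
  # F2-exclusive body: drop bases overlapping any opposite-strand trio gene
  excl <- seq.int(mid$start, mid$end - 1)
  partners <- c(as.character(trio$gene1), as.character(trio$gene3))
  for (pid in setdiff(partners, mid$gene_id)) {
    pg <- by_id[[pid]]
    if (is.null(pg) || pg$strand == mid$strand) next
    excl <- excl[excl < pg$start | excl >= pg$end]
  }
  if (length(excl) == 0L)
    stop("middle gene fully contained in opposite-strand partners")
  frac <- mean(covered[excl - pos0 + 1])
  in_flank <- seq.int(flank$start, flank$end - 1) - pos0 + 1
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  contiguous <- FALSE
  for (k in which(runs$values)) {
    run_pos <- seq.int(starts[k], ends[k]) + pos0 - 1
    if (any(run_pos >= flank$start & run_pos < flank$end) &&
        any(run_pos %in% excl)) {
      contiguous <- TRUE
      break
    }
  }
  ov_mid <- reads$chrom == mid$chrom & reads$start < mid$end &
    reads$end > mid$start
  n_anti <- sum(ov_mid & reads$strand != mid$strand)
  n_sense <- sum(ov_mid & reads$strand == mid$strand)
  ratio <- if (n_anti == 0) 0
           else if (n_sense == 0) Inf
           else n_anti / n_sense
  structure(list(
    pattern = as.character(trio$pattern),
    middle_gene = mid$gene_id, flank_gene = flank$gene_id,
    antisense_fraction_f2 = frac, contiguous_with_r3 = contiguous,
    sense_antisense_ratio_f2 = ratio,
    is_readthrough = contiguous && frac >= min_fraction && ratio >= min_ratio,
    min_depth = min_depth, min_fraction = min_fraction,
    min_ratio = min_ratio),
    class = "readthrough_call")
}

#' @export
print.readthrough_call <- function(x, ...) {
  cat(sprintf(paste0("<readthrough_call> %s middle=%s flank=%s\n",
                     "  antisense fraction %.3f, contiguous %s, ",
                     "anti/sense ratio %.3g -> readthrough: %s\n"),
              x$pattern, x$middle_gene, x$flank_gene,
              x$antisense_fraction_f2, x$contiguous_with_r3,
              x$sense_antisense_ratio_f2, x$is_readthrough))
  invisible(x)
}

#' Predict the consequence of a splice-acceptor variant
#'
#' Strand-aware: for every intron, the canonical acceptor dinucleotide (AG)
#' occupies the last two intronic bases before the downstream exon in
#' transcription order. A variant hitting the base immediately adjacent to
#' the exon is `acceptor_minus1` (c.X-1), the next one out `acceptor_minus2`
#' (c.X-2). When the downstream exon is the terminal exon, the predicted
#' outcome is skipping of that exon together with the polyA transcription
#' termination signal (`terminal_exon_skipped_polyA_lost`); otherwise
#' `internal_exon_skipped`.
#'
#' @param gene a [gene_model()] with at least 2 exons.
#' @param variant_pos 0-based genomic position of the variant.
#' @return List with `variant_pos`, `hit` (`acceptor_minus1`,
#'   `acceptor_minus2` or `none`), `intron_index` (transcription order, `NA`
#'   when no hit), `predicted` (`terminal_exon_skipped_polyA_lost`,
#'   `internal_exon_skipped` or `none`) and `note`.
#' @export
acceptor_disruption <- function(gene, variant_pos) {
  stopifnot(inherits(gene, "gene_model"))
  k <- nrow(gene$exons)
  if (k < 2L) stop("gene must have at least 2 exons")
  none <- list(variant_pos = variant_pos, hit = "none",
               intron_index = NA_integer_, predicted = "none", note = "")
  if (variant_pos < gene$start || variant_pos >= gene$end) {
    none$note <- "variant outside gene span"
    return(none)
  }
  for (t in seq_len(k - 1L)) {  # intron index in transcription order
    if (gene$strand == "+") {
      down <- t + 1L            # genomic index of downstream exon
      a1 <- gene$exons$start[down] - 1
      a2 <- gene$exons$start[down] - 2
      terminal <- down == k
    } else {
      down <- k - t             # downstream exon lies genomically left
      a1 <- gene$exons$end[down]
      a2 <- gene$exons$end[down] + 1
      terminal <- down == 1L
    }
    if (variant_pos == a1 || variant_pos == a2) {
      return(list(
        variant_pos = variant_pos,
        hit = if (variant_pos == a1) "acceptor_minus1" else "acceptor_minus2",
        intron_index = t,
        predicted = if (terminal) "terminal_exon_skipped_polyA_lost"
                    else "internal_exon_skipped",
        note = ""))
    }
  }
  none
}
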