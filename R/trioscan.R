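# Sense-antisense gene pair and trio scanning.
#
# All predicates work on transcript-level gene spans (not exon unions),
# matching browser-level inspection of overlap geometry. With 0-based
# half-open intervals, a plus-strand gene P has its 3' end at P.end and its
# 5' end at P.start; a minus-strand gene M has its 3' end at M.start and its
# 5' end at M.end.

genes_df <- function(genes) {
  if (length(genes) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0, "start"),
    end = vapply(genes, `[[`, 0, "end"),
    strand = vapply(genes, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
}

dedupe_genes <- function(genes) {
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) {
    warning("duplicate gene ids in input; keeping first occurrence")
    genes <- genes[!duplicated(ids)]
  }
  genes
}

empty_pairs <- function() {
  data.frame(gene_plus = character(), gene_minus = character(),
             chrom = character(), geometry = character(),
             overlap_start = numeric(), overlap_end = numeric(),
             gap = numeric(), stringsAsFactors = FALSE)
}

#' Find tail-to-tail sense-antisense gene pairs
#'
#' A plus-strand gene `P` and a minus-strand gene `M` form a tail-to-tail
#' pair when their spans overlap at both 3' ends:
#' `P.start < M.start <= P.end <= M.end`. Containment (one gene inside the
#' other) is excluded -- only end-to-end partial overlaps qualify.
#'
#' @param genes list of [gene_model()] objects (one chromosome per scan is
#'   typical; pairs are only formed within a chromosome).
#' @return Data frame with columns `gene_plus`, `gene_minus`, `chrom`,
#'   `geometry`, `overlap_start`, `overlap_end`, `gap` (`NA` for
#'   overlapping pairs).
#' @export
find_tail_to_tail <- function(genes) {
  genes <- dedupe_genes(genes)
  df <- genes_df(genes)
  plus <- df[df$strand == "+", ]
  minus <- df[df$strand == "-", ]
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty_pairs())
  idx <- expand.grid(p = seq_len(nrow(plus)), m = seq_len(nrow(minus)))
  P <- plus[idx$p, ]
  M <- minus[idx$m, ]
  hit <- P$chrom == M$chrom &
    P$start < M$start & M$start <= P$end & P$end <= M$end
  if (!any(hit)) return(empty_pairs())
  data.frame(gene_plus = P$gene_id[hit], gene_minus = M$gene_id[hit],
             chrom = P$chrom[hit], geometry = "tail_to_tail",
             overlap_start = M$start[hit], overlap_end = P$end[hit],
             gap = NA_real_, stringsAsFactors = FALSE)
}

#' Find head-to-head sense-antisense gene pairs
#'
#' A minus-strand gene `M` and a plus-strand gene `P` are head-to-head when
#' their spans overlap at both 5' ends (`M.start < P.start <= M.end <=
#' P.end`), or when they are divergent non-overlapping neighbours whose TSS
#' gap (`P.start - M.end`) is at most `promoter_window` (proximal
#' head-to-head, sharing a bidirectional promoter region).
#'
#' @inheritParams find_tail_to_tail
#' @param promoter_window maximum gap (bp) for the proximal case.
#' @return Data frame as in [find_tail_to_tail()], with `geometry` of
#'   `"head_to_head"` or `"head_to_head_proximal"`; proximal rows carry the
#'   `gap` and `NA` overlap coordinates.
#' @export
find_head_to_head <- function(genes, promoter_window = 1000) {
  genes <- dedupe_genes(genes)
  df <- genes_df(genes)
  plus <- df[df$strand == "+", ]
  minus <- df[df$strand == "-", ]
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty_pairs())
  idx <- expand.grid(p = seq_len(nrow(plus)), m = seq_len(nrow(minus)))
  P <- plus[idx$p, ]
  M <- minus[idx$m, ]
  same <- P$chrom == M$chrom
  ovl <- same & M$start < P$start & P$start <= M$end & M$end <= P$end
  gap <- P$start - M$end
  prox <- same & !ovl & gap >= 0 & gap <= promoter_window
  out <- empty_pairs()
  if (any(ovl))
    out <- rbind(out, data.frame(
      gene_plus = P$gene_id[ovl], gene_minus = M$gene_id[ovl],
      chrom = P$chrom[ovl], geometry = "head_to_head",
      overlap_start = P$start[ovl], overlap_end = M$end[ovl],
      gap = NA_real_, stringsAsFactors = FALSE))
  if (any(prox))
    out <- rbind(out, data.frame(
      gene_plus = P$gene_id[prox], gene_minus = M$gene_id[prox],
      chrom = P$chrom[prox], geometry = "head_to_head_proximal",
      overlap_start = NA_real_, overlap_end = NA_real_,
      gap = gap[prox], stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

promoter_window_interval <- function(tss, window) {
  c(max(0, tss - window), tss + window + 1)  # half-open, TSS +/- window
}

#' Find reverse-forward-reverse (and mirrored) gene trios
#'
#' Scans for the two trio configurations around a bidirectional-promoter
#' CpG island: `R1F2R3` -- a forward middle gene `F2` tail-to-tail with a
#' downstream reverse gene `R3` and head-to-head (overlapping or proximal)
#' with an upstream reverse gene `R1`, with at least one CpG island
#' overlapping both the `R1` and `F2` promoter windows (TSS +/-
#' `promoter_window`); and the strand-mirrored `F1R2F1`. Each trio is
#' reported once with the island of maximal joint promoter overlap.
#'
#' @param genes list of [gene_model()] objects.
#' @param islands [genomic_intervals()] of CpG islands (strandless; strand
#'   column is ignored).
#' @param promoter_window promoter half-window in bp.
#' @return Data frame with columns `pattern` (`"R1F2R3"` or `"F1R2F1"`),
#'   `gene1`, `gene2`, `gene3` (genomic order), `chrom`, `island_start`,
#'   `island_end`, `promoter_window`, `joint_overlap`.
#' @export
find_trios <- function(genes, islands, promoter_window = 1000) {
  genes <- dedupe_genes(genes)
  by_id <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  tt <- find_tail_to_tail(genes)
  hh <- find_head_to_head(genes, promoter_window)
  out <- data.frame(pattern = character(), gene1 = character(),
                    gene2 = character(), gene3 = character(),
                    chrom = character(), island_start = numeric(),
                    island_end = numeric(), promoter_window = numeric(),
                    joint_overlap = numeric(), stringsAsFactors = FALSE)
  if (nrow(tt) == 0L || nrow(hh) == 0L || nrow(islands) == 0L) return(out)

  best_island <- function(chrom, tss1, tss2) {
    w1 <- promoter_window_interval(tss1, promoter_window)
    w2 <- promoter_window_interval(tss2, promoter_window)
    ov1 <- overlap_length(islands, chrom, w1[1], w1[2])
    ov2 <- overlap_length(islands, chrom, w2[1], w2[2])
    joint <- ifelse(ov1 > 0 & ov2 > 0, ov1 + ov2, 0)
    if (all(joint == 0)) return(NULL)
    k <- which.max(joint)
    list(start = islands$start[k], end = islands$end[k], joint = joint[k])
  }

  for (i in seq_len(nrow(tt))) {
    f2 <- by_id[[tt$gene_plus[i]]]   # middle candidate for R1F2R3
    r3 <- by_id[[tt$gene_minus[i]]]
    # R1F2R3: an R1 head-to-head with F2 (R1 is the minus gene of hh rows)
    cand <- hh[hh$gene_plus == f2$gene_id & hh$gene_minus != r3$gene_id, ]
    for (j in seq_len(nrow(cand))) {
      r1 <- by_id[[cand$gene_minus[j]]]
      isl <- best_island(f2$chrom, gene_tss(r1), gene_tss(f2))
      if (is.null(isl)) next
      out <- rbind(out, data.frame(
        pattern = "R1F2R3", gene1 = r1$gene_id, gene2 = f2$gene_id,
        gene3 = r3$gene_id, chrom = f2$chrom, island_start = isl$start,
        island_end = isl$end, promoter_window = promoter_window,
        joint_overlap = isl$joint, stringsAsFactors = FALSE))
    }
    # F1R2F1: the minus gene of a tail-to-tail pair is the middle (R2);
    # its head-to-head partner F1b lies genomically downstream
    r2 <- r3
    f1a <- f2
    cand <- hh[hh$gene_minus == r2$gene_id & hh$gene_plus != f1a$gene_id, ]
    for (j in seq_len(nrow(cand))) {
      f1b <- by_id[[cand$gene_plus[j]]]
      isl <- best_island(r2$chrom, gene_tss(r2), gene_tss(f1b))
      if (is.null(isl)) next
      out <- rbind(out, data.frame(
        pattern = "F1R2F1", gene1 = f1a$gene_id, gene2 = r2$gene_id,
        gene3 = f1b$gene_id, chrom = r2$chrom, island_start = isl$start,
        island_end = isl$end, promoter_window = promoter_window,
        joint_overlap = isl$joint, stringsAsFactors = FALSE))
    }
  }
  if (nrow(out) > 1L) {
    key <- paste(out$pattern, out$gene1, out$gene2, out$gene3)
    out <- out[order(key, -out$joint_overlap), ]
    out <- out[!duplicated(paste(out$pattern, out$gene1, out$gene2,
                                 out$gene3)), ]
  }
  rownames(out) <- NULL
  out
}

#' Summarize trio patterns
#'
#' @param trios output of [find_trios()].
#' @return Data frame with one row per pattern (`R1F2R3`, `F1R2F1`) and its
#'   count.
#' @export
summarize_patterns <- function(trios) {
  data.frame(pattern = c("R1F2R3", "F1R2F1"),
             n = c(sum(trios$pattern == "R1F2R3"),
                   sum(trios$pattern == "F1R2F1")),
             stringsAsFactors = FALSE)
}
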