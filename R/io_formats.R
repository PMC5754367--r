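#' Read a BED3/BED6 file
#'
#' BED is 0-based half-open, which matches the package-internal convention,
#' so coordinates are taken verbatim. For 3-column input the strand defaults
#' to `"+"` (with a warning, since strand is mandatory internally).
#'
#' @param path path to a tab-separated BED file. Lines starting with `#`,
#'   `track` or `browser` are skipped.
#' @param columns 3 or 6: the minimum number of columns each row must carry.
#' @return A [genomic_intervals()] data frame (possibly 0 rows).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tx\t0\t-", f)
#' read_bed(f, columns = 6)
#' @export
read_bed <- function(path, columns = 6) {
  if (!columns %in% c(3, 6)) stop("columns must be 3 or 6")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < columns))
    stop(sprintf("malformed BED row at line %d: expected >= %d fields, got %d",
                 lineno[which(nf < columns)[1]], columns, min(nf)))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("malformed BED row at line %d: non-numeric coordinate",
                 lineno[which(is.na(start) | is.na(end))[1]]))
  bad <- end <= start
  if (any(bad))
    stop(sprintf("invalid BED interval at line %d: end <= start",
                 lineno[which(bad)[1]]))
  if (columns == 6) {
    name <- vapply(fields, `[[`, "", 4L)
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    strand <- vapply(fields, `[[`, "", 6L)
    badstr <- !strand %in% c("+", "-")
    if (any(badstr))
      stop(sprintf("invalid strand at line %d: '%s'",
                   lineno[which(badstr)[1]], strand[which(badstr)[1]]))
  } else {
    warning("BED3 input carries no strand; defaulting to '+'")
    name <- NA_character_
    score <- 0
    strand <- "+"
  }
  genomic_intervals(chrom, start, end, strand, name, score)
}

#' Write intervals as BED6
#'
#' @param x a [genomic_intervals()] data frame.
#' @param path output path. UTF-8, LF line endings.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  name <- ifelse(is.na(x$name), ".", x$name)
  score <- if (is.null(x$score)) 0 else x$score
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   name, score, x$strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Gene model constructor
#'
#' A gene model is a transcript-level interval plus an ordered, non-overlapping
#' exon list on the same chromosome and strand. The transcription start site
#' (TSS) is `start` on the plus strand and `end - 1` on the minus strand; the
#' 3' end (TES) is mirrored.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open gene span.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with columns `start`, `end` (0-based half-open);
#'   defaults to the full gene span as a single exon.
#' @return An object of class `gene_model`.
#' @examples
#' g <- gene_model("MMACHC", "chr1", 100, 600, "+")
#' gene_tss(g)
#' @export
gene_model <- function(gene_id, chrom, start, end, strand,
                       exons = NULL) {
  if (is.null(exons) || nrow(exons) == 0L)
    exons <- data.frame(start = start, end = end)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start))
    stop("gene ", gene_id, ": exon end <= start")
  if (any(exons$start < start) || any(exons$end > end))
    stop("gene ", gene_id, ": exon outside gene span")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("gene ", gene_id, ": overlapping exons")
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 strand = strand, exons = exons),
            class = "gene_model")
}

#' @rdname gene_model
#' @param gene a `gene_model`.
#' @export
gene_tss <- function(gene) {
  if (gene$strand == "+") gene$start else gene$end - 1
}

#' @rdname gene_model
#' @export
gene_tes <- function(gene) {
  if (gene$strand == "+") gene$end - 1 else gene$start
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s)\n", x$gene_id,
              x$chrom, as.integer(x$start), as.integer(x$end), x$strand,
              nrow(x$exons)))
  invisible(x)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 rows are 1-based inclusive and are converted to the internal 0-based
#' half-open convention at this boundary (`start - 1`, `end`). Only `gene` and
#' `exon` features are consumed; exons attach to genes via `Parent=`.
#' BED12 rows are already 0-based half-open; exons are reconstructed from
#' `blockStarts`/`blockSizes` relative to `chromStart`.
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"bed12"`.
#' @return A list of [gene_model()] objects, in file order of gene definitions.
#' @export
read_gene_models <- function(path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect, gff3 = read_gff3_genes(path), bed12 = read_bed12_genes(path))
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
}

read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L))
    stop("malformed GFF3 row: fewer than 9 fields")
  tab <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    type = vapply(fields, `[[`, "", 3L),
    start = as.numeric(vapply(fields, `[[`, "", 4L)) - 1,  # 1-based -> 0-based
    end = as.numeric(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L),
    attrs = vapply(fields, `[[`, "", 9L),
    stringsAsFactors = FALSE
  )
  genes <- tab[tab$type == "gene", ]
  exons <- tab[tab$type == "exon", ]
  gene_ids <- gff3_attr(genes$attrs, "ID")
  if (anyNA(gene_ids)) stop("GFF3 gene row lacking ID attribute")
  parents <- gff3_attr(exons$attrs, "Parent")
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex <- exons[!is.na(parents) & parents == gene_ids[i], c("start", "end")]
    out[[i]] <- gene_model(gene_ids[i], genes$chrom[i], genes$start[i],
                           genes$end[i], genes$strand[i],
                           exons = if (nrow(ex)) ex else NULL)
  }
  out
}

read_bed12_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12L))
    stop("malformed BED12 row: fewer than 12 fields")
  lapply(fields, function(f) {
    chrom_start <- as.numeric(f[2L])
    sizes <- as.numeric(strsplit(f[11L], ",")[[1]])
    starts <- as.numeric(strsplit(f[12L], ",")[[1]])
    if (length(sizes) != length(starts))
      stop("BED12 blockSizes/blockStarts length mismatch for ", f[4L])
    ex <- data.frame(start = chrom_start + starts,
                     end = chrom_start + starts + sizes)
    gene_model(f[4L], f[1L], chrom_start, as.numeric(f[3L]), f[6L], exons = ex)
  })
}

#' Write gene models as GFF3
#'
#' Emits one `gene` row and its `exon` rows per model, converting back to
#' 1-based inclusive coordinates so a read/write cycle preserves the printed
#' coordinates exactly.
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    lines <- c(lines, sprintf("%s\tepitrio\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, as.integer(g$start) + 1L,
                              as.integer(g$end), g$strand, g$gene_id))
    for (j in seq_len(nrow(g$exons))) {
      lines <- c(lines,
                 sprintf("%s\tepitrio\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$chrom, as.integer(g$exons$start[j]) + 1L,
                         as.integer(g$exons$end[j]), g$strand, g$gene_id, j,
                         g$gene_id))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Beta-value matrix constructor
#'
#' Subjects-by-probes methylation beta values in `[0, 1]` with genomic probe
#' coordinates. Probes are sorted by `(chrom, pos)`; missing values are `NA`
#' and are excluded from all downstream means and tests.
#'
#' @param probes data frame with columns `probe_id`, `chrom`, `pos`.
#' @param values numeric matrix, subjects in rows, probes in columns (column
#'   order matching `probes`).
#' @param subjects character vector of subject ids (row order of `values`).
#' @return Object of class `beta_matrix` with elements `probes`, `subjects`,
#'   `values` (dimnames set to subject / probe ids).
#' @export
beta_matrix <- function(probes, values, subjects) {
  stopifnot(is.matrix(values), nrow(values) == length(subjects),
            ncol(values) == nrow(probes))
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id in beta matrix")
  if (anyDuplicated(subjects))
    stop("duplicate subject id in beta matrix")
  rng <- range(values, na.rm = TRUE)
  if (!all(is.na(values)) && (rng[1] < 0 || rng[2] > 1))
    stop("beta values must lie in [0, 1]")
  ord <- order(probes$chrom, probes$pos)
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  values <- values[, ord, drop = FALSE]
  dimnames(values) <- list(subjects, probes$probe_id)
  structure(list(probes = probes, subjects = as.character(subjects),
                 values = values),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d subjects x %d probes, %d missing values\n",
              length(x$subjects), nrow(x$probes), sum(is.na(x$values))))
  invisible(x)
}

#' Read a beta-value matrix TSV
#'
#' Expected header: `probe_id`, `chrom`, `pos`, then one column per subject.
#' Rows are probes. Empty cells are missing values.
#'
#' @param path input TSV.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"))
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(tab)[1:3]))
    stop("beta-matrix TSV must start with columns: probe_id, chrom, pos")
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe_id: ",
         tab$probe_id[anyDuplicated(tab$probe_id)][1])
  subj <- setdiff(names(tab), need)
  vals <- suppressWarnings(
    vapply(subj, function(s) as.numeric(tab[[s]]), numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(tab$probe_id, subj))
  out_of_range <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(out_of_range))
    stop("beta value outside [0, 1] at probe ",
         tab$probe_id[which(rowSums(out_of_range) > 0)[1]])
  beta_matrix(
    probes = data.frame(probe_id = tab$probe_id, chrom = tab$chrom,
                        pos = as.numeric(tab$pos), stringsAsFactors = FALSE),
    values = t(vals), subjects = subj)
}

#' Write a beta-value matrix TSV
#'
#' @param bm a [beta_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path) {
  stopifnot(inherits(bm, "beta_matrix"))
  vals <- t(bm$values)  # probes in rows
  body <- apply(vals, 2, function(col)
    ifelse(is.na(col), "", vapply(col, function(v) sprintf("%.17g", v), "")))
  body <- matrix(body, nrow = nrow(vals))
  header <- paste(c("probe_id", "chrom", "pos", bm$subjects), collapse = "\t")
  rows <- apply(cbind(bm$probes$probe_id, bm$probes$chrom,
                      format(bm$probes$pos, scientific = FALSE, trim = TRUE),
                      body),
                1, paste, collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
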