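#' Build a bisulfite region reference
#'
#' Enumerates CpG cytosines and non-CpG cytosines of an assayed region by a
#' single left-to-right scan. Non-CpG cytosines are the substrate of the
#' bisulfite conversion-efficiency QC; CpG cytosines carry the methylation
#' signal. A cytosine at the last position of the sequence counts as non-CpG.
#' An optional tagging SNP (e.g. a promoter G/T polymorphism) lets clones be
#' assigned to parental alleles; the SNP must be methylation-neutral, i.e. it
#' may not coincide with a CpG cytosine. A SNP that lands on a non-CpG
#' cytosine is removed from the QC position set so that allele base calls
#' cannot masquerade as conversion failures.
#'
#' @param seq DNA string of the region (A/C/G/T/N), case-insensitive.
#' @param region optional single-row [genomic_intervals()] locating the
#'   region; its width must equal `nchar(seq)`.
#' @param snp_offset optional 0-based offset of the tagging SNP within `seq`.
#' @param snp_alleles length-2 character vector `(tag base, other base)`;
#'   required when `snp_offset` is given.
#' @return Object of class `region_reference` with fields `seq`, `region`,
#'   `cpg_positions`, `noncpg_c_positions` (0-based offsets), `snp_offset`,
#'   `snp_alleles`.
#' @examples
#' build_reference("ACGTCA")  # one CpG at offset 1, one non-CpG C at 4
#' @export
build_reference <- function(seq, region = NULL, snp_offset = NULL,
                            snp_alleles = NULL) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("reference sequence contains non-ACGTN characters")
  if (!is.null(region)) {
    validate_intervals(region)
    if (interval_width(region)[1] != length(chars))
      stop("region width does not match sequence length")
  }
  is_c <- chars == "C"
  next_g <- c(chars[-1] == "G", FALSE)
  cpg <- which(is_c & next_g) - 1L      # 0-based
  noncpg <- which(is_c & !next_g) - 1L
  if (!is.null(snp_offset)) {
    if (is.null(snp_alleles) || length(snp_alleles) != 2L)
      stop("snp_alleles must give the (tag, other) base pair")
    snp_alleles <- toupper(snp_alleles)
    if (snp_offset %in% cpg)
      stop("tagging SNP coincides with a CpG cytosine; tag must be ",
           "methylation-neutral")
    noncpg <- setdiff(noncpg, snp_offset)
  }
  structure(list(seq = seq, region = region,
                 cpg_positions = as.integer(cpg),
                 noncpg_c_positions = as.integer(noncpg),
                 snp_offset = if (is.null(snp_offset)) NULL
                              else as.integer(snp_offset),
                 snp_alleles = snp_alleles),
            class = "region_reference")
}

#' @export
print.region_reference <- function(x, ...) {
  cat(sprintf("<region_reference> %d bp, %d CpG sites, %d non-CpG C, %s\n",
              nchar(x$seq), length(x$cpg_positions),
              length(x$noncpg_c_positions),
              if (is.null(x$snp_offset)) "no tag SNP"
              else sprintf("tag SNP %s/%s at offset %d", x$snp_alleles[1],
                           x$snp_alleles[2], x$snp_offset)))
  invisible(x)
}

#' Call methylation for one bisulfite clone
#'
#' The clone must be pre-aligned to the reference (equal length, no indels;
#' Sanger-sequenced cloned amplicons). At each CpG cytosine, `C` calls
#' methylated (1), `T` unmethylated (0), anything else missing. At each
#' non-CpG cytosine, `T` counts as converted and `C` as unconverted; the
#' conversion rate is converted / (converted + unconverted) and a clone
#' passes QC only when the rate is strictly greater than `conversion_min`
#' (the ">95% converted" filter). The allele is assigned by exact match of
#' the base at the SNP offset against the reference's tag/other alleles.
#'
#' @param clone_seq clone DNA string, same length as the reference.
#' @param ref a [build_reference()] object.
#' @param clone_id identifier stored in the call.
#' @param conversion_min QC threshold; pass requires rate `>` this value.
#' @return Object of class `clone_call`: `clone_id`, `meth_calls` (integer
#'   0/1/NA per CpG), `conversion_rate`, `allele` (`"tag"`, `"other"` or
#'   `"unassigned"`), `passed_qc`.
#' @export
call_clone <- function(clone_seq, ref, clone_id = "clone",
                       conversion_min = 0.95) {
  stopifnot(inherits(ref, "region_reference"))
  clone_seq <- toupper(clone_seq)
  if (nchar(clone_seq) != nchar(ref$seq))
    stop("clone length (", nchar(clone_seq), ") does not match reference (",
         nchar(ref$seq), ")")
  chars <- strsplit(clone_seq, "", fixed = TRUE)[[1]]
  cpg_base <- chars[ref$cpg_positions + 1L]
  meth <- ifelse(cpg_base == "C", 1L, ifelse(cpg_base == "T", 0L, NA_integer_))
  qc_base <- chars[ref$noncpg_c_positions + 1L]
  converted <- sum(qc_base == "T")
  unconverted <- sum(qc_base == "C")
  if (converted + unconverted == 0L)
    stop("no assessable non-CpG cytosines; conversion QC indeterminate")
  rate <- converted / (converted + unconverted)
  allele <- "unassigned"
  if (!is.null(ref$snp_offset)) {
    b <- chars[ref$snp_offset + 1L]
    if (b == ref$snp_alleles[1]) allele <- "tag"
    else if (b == ref$snp_alleles[2]) allele <- "other"
  }
  structure(list(clone_id = clone_id, meth_calls = meth,
                 conversion_rate = rate, allele = allele,
                 passed_qc = rate > conversion_min),
            class = "clone_call")
}

#' Assemble an epigram from clone calls
#'
#' Drops QC-failed clones (reporting how many) and computes the mean
#' methylation fraction per allele group over all non-missing CpG calls.
#'
#' @param clone_calls list of [call_clone()] results.
#' @param ref the shared [build_reference()].
#' @return Object of class `epigram`: `clones` (QC-passed calls),
#'   `reference`, `allele_fractions` (named mean methylation per allele
#'   group present), `allele_counts`, `n_dropped`.
#' @export
assemble_epigram <- function(clone_calls, ref) {
  stopifnot(inherits(ref, "region_reference"))
  passed <- Filter(function(cl) isTRUE(cl$passed_qc), clone_calls)
  n_drop <- length(clone_calls) - length(passed)
  if (length(passed) == 0L)
    stop("no clones passed conversion QC (", n_drop, " dropped)")
  if (n_drop > 0L)
    message(n_drop, " clone(s) dropped by conversion QC")
  alleles <- vapply(passed, `[[`, "", "allele")
  groups <- split(passed, alleles)
  fr <- vapply(groups, function(g) {
    calls <- unlist(lapply(g, `[[`, "meth_calls"))
    mean(calls, na.rm = TRUE)
  }, numeric(1))
  structure(list(clones = passed, reference = ref,
                 allele_fractions = fr,
                 allele_counts = vapply(groups, length, integer(1)),
                 n_dropped = n_drop),
            class = "epigram")
}

#' @export
print.epigram <- function(x, ...) {
  cat(sprintf("<epigram> %d QC-passed clone(s) (%d dropped), %d CpG sites\n",
              length(x$clones), x$n_dropped,
              length(x$reference$cpg_positions)))
  for (a in names(x$allele_fractions))
    cat(sprintf("  allele %-10s n=%d  methylation fraction %.3f\n", a,
                x$allele_counts[[a]], x$allele_fractions[[a]]))
  invisible(x)
}

#' Call a mono-allelic epimutation from an epigram
#'
#' An allele carries the epimutation when its methylation fraction is at
#' least `hyper_min` while the opposite allele's fraction is at most
#' `hypo_max`, with at least `min_clones_per_allele` clones observed on each
#' allele. When both alleles are at most `hypo_max` the call is `"none"`;
#' anything else is `"indeterminate"`. The returned `call` is the SNP base of
#' the hypermethylated allele (e.g. `"G"`), not the group label.
#'
#' @param epigram an [assemble_epigram()] result with allele-tagged clones.
#' @param hyper_min minimum methylation fraction of the epimutated allele.
#' @param hypo_max maximum fraction of the normal allele.
#' @param min_clones_per_allele minimum clones per allele for a positive call.
#' @return List with `call` (allele base, `"none"` or `"indeterminate"`),
#'   `fractions` and `counts` for the tag/other groups.
#' @export
call_monoallelic_epimutation <- function(epigram, hyper_min = 0.9,
                                         hypo_max = 0.1,
                                         min_clones_per_allele = 3) {
  stopifnot(inherits(epigram, "epigram"))
  ref <- epigram$reference
  if (is.null(ref$snp_offset))
    stop("epigram reference has no tagging SNP; cannot resolve alleles")
  f_tag <- epigram$allele_fractions[["tag"]]
  f_oth <- epigram$allele_fractions[["other"]]
  n_tag <- epigram$allele_counts[["tag"]]
  n_oth <- epigram$allele_counts[["other"]]
  if (is.null(n_tag) && is.null(n_oth) ||
      (is.null(n_tag) || n_tag == 0L) && (is.null(n_oth) || n_oth == 0L))
    stop("no clones assigned to either allele")
  n_tag <- if (is.null(n_tag)) 0L else n_tag
  n_oth <- if (is.null(n_oth)) 0L else n_oth
  f_tag <- if (is.null(f_tag)) NA_real_ else f_tag
  f_oth <- if (is.null(f_oth)) NA_real_ else f_oth
  enough <- n_tag >= min_clones_per_allele && n_oth >= min_clones_per_allele
  call <- "indeterminate"
  if (!is.na(f_tag) && !is.na(f_oth)) {
    if (enough && f_tag >= hyper_min && f_oth <= hypo_max)
      call <- ref$snp_alleles[1]
    else if (enough && f_oth >= hyper_min && f_tag <= hypo_max)
      call <- ref$snp_alleles[2]
    else if (f_tag <= hypo_max && f_oth <= hypo_max)
      call <- "none"
  }
  list(call = call,
       fractions = c(tag = f_tag, other = f_oth),
       counts = c(tag = n_tag, other = n_oth))
}

#' Read bisulfite clones from FASTA
#'
#' @param path FASTA file; headers (up to the first whitespace) are clone ids.
#' @return Named character vector of uppercase clone sequences.
#' @export
read_clones <- function(path) read_fasta_seqs(path)

#' Write an epigram table
#'
#' TSV with one row per QC-passed clone: `clone_id`, `allele`,
#' `conversion_rate`, then one 0/1/NA column per CpG site (named by offset).
#'
#' @param epigram an [assemble_epigram()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epigram <- function(epigram, path) {
  stopifnot(inherits(epigram, "epigram"))
  cpg <- epigram$reference$cpg_positions
  meth <- t(vapply(epigram$clones, `[[`, integer(length(cpg)), "meth_calls"))
  df <- data.frame(
    clone_id = vapply(epigram$clones, `[[`, "", "clone_id"),
    allele = vapply(epigram$clones, `[[`, "", "allele"),
    conversion_rate = vapply(epigram$clones, `[[`, 0, "conversion_rate"))
  meth <- as.data.frame(meth)
  names(meth) <- paste0("cpg_", cpg)
  write_tsv(cbind(df, meth), path)
}
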