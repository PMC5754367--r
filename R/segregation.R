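# Rare damaging variant filtering and co-segregation with epimutation
# carrier status.

DAMAGE_CLASSES <- c("nonsense", "splice_site", "frameshift_indel", "missense")

#' Read a variant table
#'
#' TSV with fixed columns `chrom`, `pos` (1-based, as variant tables print),
#' `ref`, `alt`, `consequence`, `max_maf`, followed by one genotype column
#' per sample with values in `hom_ref`, `het`, `hom_alt`, `missing` (empty
#' cells also count as missing).
#'
#' @param path input TSV.
#' @return Data frame; the sample (genotype) column names are attached as
#'   attribute `samples`.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "consequence", "max_maf")
  if (!all(need %in% names(tab)))
    stop("variant TSV must carry columns: ", paste(need, collapse = ", "))
  tab$pos <- as.numeric(tab$pos)
  tab$max_maf <- as.numeric(tab$max_maf)
  if (any(is.na(tab$max_maf)) || any(tab$max_maf < 0 | tab$max_maf > 1))
    stop("max_maf must lie in [0, 1]")
  samples <- setdiff(names(tab), need)
  for (s in samples) {
    g <- tab[[s]]
    g[is.na(g) | g == ""] <- "missing"
    bad <- !g %in% c("hom_ref", "het", "hom_alt", "missing")
    if (any(bad)) stop("invalid genotype '", g[bad][1], "' for sample ", s)
    tab[[s]] <- g
  }
  attr(tab, "samples") <- samples
  tab
}

#' Read a carrier status map
#'
#' Two-column TSV `sample`, `status` with status `carrier` / `non_carrier`.
#'
#' @param path input TSV.
#' @return Named character vector (names = sample ids).
#' @export
read_status_map <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample", "status") %in% names(tab)))
    stop("status TSV must carry columns: sample, status")
  bad <- !tab$status %in% c("carrier", "non_carrier")
  if (any(bad)) stop("invalid status: ", tab$status[bad][1])
  stats::setNames(tab$status, tab$sample)
}

#' Filter variants by damage class and rarity
#'
#' Keeps the most likely protein-damaging classes (nonsense, splice site,
#' frameshift indel, missense) and removes variants whose maximum population
#' allele frequency exceeds `maf_max` -- strictly greater than 0.001 is
#' removed, exactly 0.001 is kept.
#'
#' @param variants data frame from [read_variant_table()] (or the same
#'   shape).
#' @param maf_max maximum population MAF retained.
#' @param classes consequence classes retained.
#' @return The filtered data frame (attributes preserved).
#' @export
filter_variants <- function(variants, maf_max = 0.001,
                            classes = DAMAGE_CLASSES) {
  keep <- variants$consequence %in% classes & variants$max_maf <= maf_max
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- attr(variants, "samples")
  out
}

#' Co-segregation of variants with epimutation carrier status
#'
#' Under the default dominant heterozygous model a variant segregates when
#' it is `het` in every carrier and `hom_ref` in every non-carrier. In
#' strict mode (default) a `missing` genotype in any pedigree sample fails
#' the variant; in lenient mode missing genotypes are skipped (and the
#' relaxation is noted via `message()`).
#'
#' @param variants data frame from [read_variant_table()] /
#'   [filter_variants()].
#' @param status named status vector from [read_status_map()] (values
#'   `carrier` / `non_carrier`); every named sample must have a genotype
#'   column.
#' @param model only `"het_in_carriers"` is implemented.
#' @param missing_mode `"strict"` or `"lenient"`.
#' @return The segregating subset of `variants`.
#' @export
cosegregate <- function(variants, status,
                        model = c("het_in_carriers"),
                        missing_mode = c("strict", "lenient")) {
  model <- match.arg(model)
  missing_mode <- match.arg(missing_mode)
  carriers <- names(status)[status == "carrier"]
  noncarriers <- names(status)[status == "non_carrier"]
  if (length(carriers) == 0L)
    stop("status map contains no carriers; a discriminating scan needs both")
  if (length(noncarriers) == 0L)
    stop("status map contains no non-carriers")
  absent <- setdiff(names(status), names(variants))
  if (length(absent) > 0L)
    stop("no genotype column for sample(s): ", paste(absent, collapse = ", "))
  if (missing_mode == "lenient")
    message("lenient mode: missing genotypes ignored in segregation checks")
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    g <- unlist(variants[i, names(status)], use.names = TRUE)
    if (missing_mode == "strict" && any(g == "missing")) return(FALSE)
    gc <- g[carriers]
    gn <- g[noncarriers]
    if (missing_mode == "lenient") {
      gc <- gc[gc != "missing"]
      gn <- gn[gn != "missing"]
    }
    all(gc == "het") && all(gn == "hom_ref")
  }, logical(1))
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- attr(variants, "samples")
  out
}
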