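#' Genomic intervals (0-based half-open)
#'
#' Constructs a validated data frame of genomic intervals. All coordinates in
#' this package are 0-based half-open: an interval covers bases
#' `start, ..., end - 1`. Strand is mandatory internally and must be `"+"` or
#' `"-"`; strandless input formats default to `"+"` at the parse boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts (`>= 0`).
#' @param end integer vector, 0-based exclusive ends (`> start`).
#' @param strand character vector in `{"+", "-"}` (recycled).
#' @param name optional feature names (recycled; `NA` allowed).
#' @param score optional numeric scores (recycled).
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `score`, of class `c("genomic_intervals", "data.frame")`.
#' @examples
#' genomic_intervals("chr1", 10, 20, "-")
#' @export
genomic_intervals <- function(chrom, start, end, strand = "+",
                              name = NA_character_, score = 0) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval coordinates must not be NA")
  if (any(df$start < 0))
    stop("interval start must be >= 0")
  if (any(df$end <= df$start))
    stop("interval end must be > start (0-based half-open)")
  bad <- !df$strand %in% c("+", "-")
  if (any(bad))
    stop("strand must be '+' or '-', got: ",
         paste(unique(df$strand[bad]), collapse = ", "))
  invisible(df)
}

# width of each interval in bases
interval_width <- function(df) df$end - df$start

# TRUE where interval rows i (df a) overlap interval b (single row), ignoring strand
overlaps_interval <- function(df, chrom, start, end) {
  df$chrom == chrom & df$start < end & df$end > start
}

# length of pairwise overlap between one interval and rows of df (0 if none)
overlap_length <- function(df, chrom, start, end) {
  len <- pmin(df$end, end) - pmax(df$start, start)
  len[df$chrom != chrom | len < 0] <- 0
  len
}
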