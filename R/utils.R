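# Internal helpers shared across modules.

#' Round a positive number up to one significant figure
#'
#' Used for "not higher than"-style frequency ceilings, e.g.
#' 4.81e-4 -> 5e-4. Zero maps to zero.
#'
#' @param x non-negative number.
#' @return `x` rounded up to one significant figure.
#' @keywords internal
#' @noRd
sigfig_ceiling <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x), x >= 0)
  if (x == 0) return(0)
  e <- floor(log10(x))
  m <- x / 10^e
  # guard against 5.000000001 from floating division of an exact 5e-4
  ceiling(m - 1e-9) * 10^e
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a 31-bit sub-seed for one generator stream.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587)
}

# Read a FASTA file into a named uppercase character vector.
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# Write a named character vector of sequences as FASTA (LF endings).
write_fasta_seqs <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
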