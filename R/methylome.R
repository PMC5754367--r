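#' Categorize beta values (ENCODE-style)
#'
#' Beta values at most 0.2 are fully unmethylated (`UU`), at least 0.6 fully
#' methylated (`MM`), and values strictly between 0.2 and 0.6 partially
#' methylated (`PM`). The three categories partition `[0, 1]`; `NA`
#' propagates.
#'
#' @param beta numeric vector of beta values in `[0, 1]` (`NA` allowed).
#' @param uu_max upper bound of the unmethylated category (inclusive).
#' @param mm_min lower bound of the fully methylated category (inclusive).
#' @return Factor with levels `UU`, `PM`, `MM`.
#' @seealso [beta_dosage()] for the 0/1/2 dosage coding used by epi-LD.
#' @examples
#' categorize_beta(c(0.2, 0.4, 0.6))
#' @export
categorize_beta <- function(beta, uu_max = 0.2, mm_min = 0.6) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop("beta values must lie in [0, 1]")
  out <- ifelse(is.na(beta), NA_character_,
                ifelse(beta <= uu_max, "UU",
                       ifelse(beta >= mm_min, "MM", "PM")))
  factor(out, levels = c("UU", "PM", "MM"))
}

#' Methylation dosage from beta values
#'
#' `UU` -> 0, `PM` -> 1, `MM` -> 2, treating the partially methylated state
#' as an unphased heterozygous epigenotype.
#'
#' @inheritParams categorize_beta
#' @return Integer vector in `{0, 1, 2}` (`NA` propagated).
#' @export
beta_dosage <- function(beta, uu_max = 0.2, mm_min = 0.6) {
  as.integer(categorize_beta(beta, uu_max, mm_min)) - 1L
}

#' Scan for methylation variation positions (MVPs)
#'
#' Per-probe case-vs-control comparison over the shared probe set:
#' signed difference of group means (`delta_beta = mean(case) -
#' mean(control)`), Welch two-sample t-statistic with two-sided p-value,
#' and Bonferroni adjustment over the tested probes. Probes whose
#' hypermethylation difference reaches `delta_threshold` are flagged
#' (`flag_hyper`); the mirrored hypomethylation flag is reported as
#' `flag_hypo`. The output columns support both the epi-Manhattan plot
#' (`delta_beta` against `pos`) and the volcano plot (`delta_beta` against
#' `-log10(p_value)`).
#'
#' @param cases,controls [beta_matrix()] objects; the probe intersection is
#'   used and mismatches are reported via `message()`.
#' @param delta_threshold flag threshold on the signed difference.
#' @return Data frame with columns `probe_id`, `chrom`, `pos`, `n_case`,
#'   `n_control`, `delta_beta`, `t_stat`, `p_value`, `p_bonferroni`,
#'   `flag_hyper`, `flag_hypo`. The Bonferroni factor `m` (number of probes
#'   with a computed p-value) is attached as attribute `m_tested`.
#' @export
mvp_scan <- function(cases, controls, delta_threshold = 0.3) {
  stopifnot(inherits(cases, "beta_matrix"), inherits(controls, "beta_matrix"))
  shared <- intersect(cases$probes$probe_id, controls$probes$probe_id)
  if (length(shared) == 0L) stop("no shared probes between cases and controls")
  n_miss <- length(union(cases$probes$probe_id, controls$probes$probe_id)) -
    length(shared)
  if (n_miss > 0L)
    message(n_miss, " probe(s) absent from one group; intersection used")
  pr <- controls$probes[match(shared, controls$probes$probe_id), ]
  ord <- order(pr$chrom, pr$pos)
  pr <- pr[ord, ]
  cs <- cases$values[, pr$probe_id, drop = FALSE]
  ct <- controls$values[, pr$probe_id, drop = FALSE]
  n_case <- colSums(!is.na(cs))
  n_control <- colSums(!is.na(ct))
  delta <- colMeans(cs, na.rm = TRUE) - colMeans(ct, na.rm = TRUE)
  delta[n_case == 0L | n_control == 0L] <- NA_real_
  t_stat <- p <- rep(NA_real_, nrow(pr))
  for (j in seq_len(nrow(pr))) {
    x <- cs[, j][!is.na(cs[, j])]
    y <- ct[, j][!is.na(ct[, j])]
    if (length(x) >= 2L && length(y) >= 2L) {
      tt <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                     error = function(e) NULL)
      if (!is.null(tt)) {
        t_stat[j] <- unname(tt$statistic)
        p[j] <- tt$p.value
      }
    }
  }
  m <- sum(!is.na(p))
  res <- data.frame(
    probe_id = pr$probe_id, chrom = pr$chrom, pos = pr$pos,
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    delta_beta = unname(delta), t_stat = t_stat, p_value = p,
    p_bonferroni = pmin(1, m * p),
    flag_hyper = !is.na(delta) & delta >= delta_threshold,
    flag_hypo = !is.na(delta) & delta <= -delta_threshold,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "m_tested") <- m
  res
}

#' Screen a cohort for epimutation carriers over a probe block
#'
#' A subject is a carrier when every non-missing probe of the block
#' categorizes as non-`UU` (beta > 0.2, default rule) -- i.e. shows the same
#' hypermethylation signature as the index cases -- or, under the strict
#' `"all_pm"` rule, when every non-missing block probe is `PM`
#' (heterozygous-like intermediate methylation). Subjects missing more than
#' half of the block probes are excluded and reported.
#'
#' @param cohort a [beta_matrix()].
#' @param block_probes character vector of probe ids (must be a subset of
#'   the cohort probes).
#' @param rule `"non_uu"` (default) or `"all_pm"`.
#' @param uu_max,mm_min category boundaries passed to [categorize_beta()].
#' @return Object of class `carrier_report`: `block_probes`, `carriers`
#'   (subject ids), `n_subjects` (evaluated), `excluded` (subject ids
#'   dropped for missingness), `rule`.
#' @export
detect_carriers <- function(cohort, block_probes, rule = c("non_uu", "all_pm"),
                            uu_max = 0.2, mm_min = 0.6) {
  rule <- match.arg(rule)
  stopifnot(inherits(cohort, "beta_matrix"))
  if (length(block_probes) == 0L) stop("block_probes must be non-empty")
  missing_probes <- setdiff(block_probes, cohort$probes$probe_id)
  if (length(missing_probes) > 0L)
    stop("block probes absent from cohort: ",
         paste(missing_probes, collapse = ", "))
  vals <- cohort$values[, block_probes, drop = FALSE]
  miss_frac <- rowMeans(is.na(vals))
  excluded <- cohort$subjects[miss_frac > 0.5]
  if (length(excluded) > 0L)
    message(length(excluded),
            " subject(s) excluded (>50% of block probes missing)")
  keep <- miss_frac <= 0.5
  vals <- vals[keep, , drop = FALSE]
  subjects <- cohort$subjects[keep]
  cat_mat <- matrix(categorize_beta(as.vector(vals), uu_max, mm_min),
                    nrow = nrow(vals))
  is_carrier <- switch(rule,
    non_uu = apply(cat_mat, 1, function(r) all(r[!is.na(r)] != "UU")),
    all_pm = apply(cat_mat, 1, function(r) all(r[!is.na(r)] == "PM")))
  structure(list(block_probes = block_probes,
                 carriers = subjects[is_carrier],
                 n_subjects = length(subjects),
                 excluded = excluded, rule = rule),
            class = "carrier_report")
}

#' @export
print.carrier_report <- function(x, ...) {
  cat(sprintf("<carrier_report> %d carrier(s) / %d subject(s), rule '%s'\n",
              length(x$carriers), x$n_subjects, x$rule))
  if (length(x$carriers)) cat("  carriers:",
                              paste(x$carriers, collapse = ", "), "\n")
  invisible(x)
}

#' Epimutation allele frequency from carrier counts
#'
#' Under the heterozygous-carrier assumption each carrier contributes one
#' epimutated allele among `2 * n_subjects` alleles. The upper bound is the
#' point estimate rounded up to one significant figure -- the
#' "not higher than" style ceiling (1 carrier / 1040 subjects gives
#' estimate 4.81e-4, bound 5e-4). With zero carriers the bound is the
#' one-carrier frequency ceiling.
#'
#' @param n_carriers number of carriers observed.
#' @param n_subjects cohort size (`>= 1`).
#' @param zygosity only `"heterozygous"` is implemented.
#' @return List with `estimate`, `upper_bound`, `n_carriers`, `n_subjects`.
#' @examples
#' allele_frequency(1, 1040)
#' @export
allele_frequency <- function(n_carriers, n_subjects,
                             zygosity = c("heterozygous")) {
  zygosity <- match.arg(zygosity)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (n_carriers < 0 || n_carriers > n_subjects)
    stop("n_carriers must lie in [0, n_subjects]")
  estimate <- n_carriers / (2 * n_subjects)
  upper <- sigfig_ceiling(max(n_carriers, 1) / (2 * n_subjects))
  list(estimate = estimate, upper_bound = min(upper, 1),
       n_carriers = n_carriers, n_subjects = n_subjects)
}
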