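#' Two-locus epihaplotype EM and epi-LD
#'
#' Estimates the four epihaplotype frequencies (UU, UM, MU, MM) between two
#' CpG probes from unphased methylation dosages in `{0, 1, 2}` via the
#' standard two-locus EM algorithm, then derives the disequilibrium
#' coefficient `D = f(MM) - pA*pB` and `r^2 = D^2 / (pA qA pB qB)`.
#' Initialization is at linkage equilibrium (products of the observed
#' methylated-allele frequencies); the E-step apportions double
#' heterozygotes (1,1) between cis (MM/UU) and trans (MU/UM) phase by the
#' current haplotype frequencies; iteration stops when the log-likelihood
#' improves by less than `tol` or after `max_iter` iterations. The
#' log-likelihood is non-decreasing by construction and is checked at every
#' iteration.
#'
#' @param g1,g2 integer dosage vectors in `{0, 1, 2}` (same length, no `NA`;
#'   drop incomplete pairs upstream).
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap.
#' @return Object of class `epi_ld` with fields `n`, `pA`, `pB`,
#'   `hap_freqs` (named UU/UM/MU/MM), `D`, `r2_em`, `loglik`, `n_iter`,
#'   `converged`. When either locus is monomorphic, `D` and `r2_em` are `NA`
#'   (undefined, never coerced to 0).
#' @seealso [chm_ld()] for the phase-free composite estimator,
#'   [ld_grid_oracle()] for a brute-force likelihood reference.
#' @export
em_ld <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  check_dosages(g1, g2)
  n <- length(g1)
  if (n < 2L) stop("need at least 2 subjects")
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  cnt <- genotype_counts(g1, g2)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    hf <- hap_products(pA, pB)
    return(structure(list(n = n, pA = pA, pB = pB, hap_freqs = hf,
                          D = NA_real_, r2_em = NA_real_,
                          loglik = genotype_loglik(cnt, hf), n_iter = 0L,
                          converged = TRUE),
                     class = "epi_ld"))
  }
  hf <- hap_products(pA, pB)
  ll_old <- genotype_loglik(cnt, hf)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cis <- hf["UU"] * hf["MM"]
    trans <- hf["UM"] * hf["MU"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    e_uu <- 2 * cnt["0,0"] + cnt["0,1"] + cnt["1,0"] + w * cnt["1,1"]
    e_um <- 2 * cnt["0,2"] + cnt["0,1"] + cnt["1,2"] + (1 - w) * cnt["1,1"]
    e_mu <- 2 * cnt["2,0"] + cnt["1,0"] + cnt["2,1"] + (1 - w) * cnt["1,1"]
    e_mm <- 2 * cnt["2,2"] + cnt["1,2"] + cnt["2,1"] + w * cnt["1,1"]
    hf <- c(UU = unname(e_uu), UM = unname(e_um), MU = unname(e_mu),
            MM = unname(e_mm)) / (2 * n)
    ll <- genotype_loglik(cnt, hf)
    if (ll < ll_old - 1e-9)
      stop("EM log-likelihood decreased; this is a bug")
    if (ll - ll_old < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  D <- unname(hf["MM"]) - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(n = n, pA = pA, pB = pB, hap_freqs = hf, D = D,
                 r2_em = unname(r2), loglik = unname(ll_old), n_iter = iter,
                 converged = converged),
            class = "epi_ld")
}

check_dosages <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("g1 and g2 must have equal length")
  if (anyNA(g1) || anyNA(g2)) stop("dosages must not contain NA")
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2))
    stop("dosages must lie in {0, 1, 2}")
  invisible(TRUE)
}

genotype_counts <- function(g1, g2) {
  cnt <- stats::setNames(numeric(9L),
                         as.vector(outer(0:2, 0:2,
                                         function(i, j) paste(i, j, sep = ","))))
  tab <- table(paste(g1, g2, sep = ","))
  cnt[names(tab)] <- as.numeric(tab)
  cnt
}

# multinomial log-likelihood of 3x3 genotype counts under random union of
# haplotypes with frequencies hf = c(UU, UM, MU, MM)
genotype_loglik <- function(cnt, hf) {
  p <- c(
    "0,0" = hf[["UU"]]^2,
    "0,1" = 2 * hf[["UU"]] * hf[["UM"]],
    "0,2" = hf[["UM"]]^2,
    "1,0" = 2 * hf[["UU"]] * hf[["MU"]],
    "1,1" = 2 * (hf[["UU"]] * hf[["MM"]] + hf[["UM"]] * hf[["MU"]]),
    "1,2" = 2 * hf[["UM"]] * hf[["MM"]],
    "2,0" = hf[["MU"]]^2,
    "2,1" = 2 * hf[["MU"]] * hf[["MM"]],
    "2,2" = hf[["MM"]]^2)
  used <- cnt > 0
  sum(cnt[used] * log(p[names(cnt)[used]]))
}

hap_products <- function(pA, pB) {
  c(UU = (1 - pA) * (1 - pB), UM = (1 - pA) * pB,
    MU = pA * (1 - pB), MM = pA * pB)
}

#' Brute-force likelihood oracle for two-locus epi-LD
#'
#' Maximizes the multinomial genotype likelihood over the 4-haplotype
#' simplex by grid search and returns the implied `r^2`. Because genotype
#' margins are phase-invariant, the simplex maximizer has allele
#' frequencies equal to the observed ones, so the search reduces exactly to
#' a 1-D grid over the MM-haplotype frequency within its Frechet bounds
#' `[max(0, pA+pB-1), min(pA, pB)]`. The grid localizes the maximizer; a
#' bracketed golden-section polish ([stats::optimize()]) within one grid
#' step then removes the discretization error, which would otherwise exceed
#' the comparison tolerance wherever `r^2` is steep in the haplotype
#' frequency. This function shares no code with [em_ld()]'s iteration and
#' serves as its independent reference.
#'
#' @inheritParams em_ld
#' @param step grid step on the MM-haplotype frequency.
#' @return List with `r2`, `p_mm`, `loglik` at the polished maximizer
#'   (`r2` is `NA` when a locus is monomorphic).
#' @export
ld_grid_oracle <- function(g1, g2, step = 1e-3) {
  check_dosages(g1, g2)
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(r2 = NA_real_, p_mm = NA_real_, loglik = NA_real_))
  cnt <- genotype_counts(g1, g2)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  profile_ll <- function(pmm) {
    hf <- c(UU = 1 - pA - pB + pmm, UM = pB - pmm, MU = pA - pmm, MM = pmm)
    hf[hf < 0] <- 0  # clamp float dust at the bounds
    genotype_loglik(cnt, hf)
  }
  grid <- unique(c(seq(lo, hi, by = step), hi))
  ll <- vapply(grid, profile_ll, numeric(1))
  best <- which.max(ll)
  opt <- stats::optimize(profile_ll,
                         lower = max(lo, grid[best] - step),
                         upper = min(hi, grid[best] + step),
                         maximum = TRUE, tol = 1e-10)
  p_mm <- if (opt$objective >= ll[best]) opt$maximum else grid[best]
  D <- p_mm - pA * pB
  list(r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       p_mm = p_mm, loglik = max(opt$objective, ll[best]))
}

#' Composite haplotype method (CHM) epi-LD
#'
#' Phase-free composite disequilibrium from genotype dosages:
#' `delta_comp = cov(g1, g2) / 2` (covariance with `1/n` normalization),
#' with within-locus Hardy-Weinberg departures `dA = freq(g1 == 2) - pA^2`
#' (and `dB` analogously) correcting the denominator:
#' `r2_chm = delta_comp^2 / ((pA qA + dA) (pB qB + dB))`.
#'
#' @inheritParams em_ld
#' @return Object of class `epi_ld` with fields `n`, `pA`, `pB`,
#'   `delta_comp`, `dA`, `dB`, `r2_chm` (`NA` with `defined = FALSE` when a
#'   locus is monomorphic or the corrected denominator vanishes).
#' @export
chm_ld <- function(g1, g2) {
  check_dosages(g1, g2)
  n <- length(g1)
  if (n < 2L) stop("need at least 2 subjects")
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  delta <- (mean(g1 * g2) - mean(g1) * mean(g2)) / 2
  dA <- mean(g1 == 2) - pA^2
  dB <- mean(g2 == 2) - pB^2
  den <- (pA * (1 - pA) + dA) * (pB * (1 - pB) + dB)
  mono <- pA %in% c(0, 1) || pB %in% c(0, 1)
  r2 <- if (mono || den <= 0) NA_real_ else delta^2 / den
  structure(list(n = n, pA = pA, pB = pB, delta_comp = delta,
                 dA = dA, dB = dB, r2_chm = r2,
                 defined = !is.na(r2)),
            class = "epi_ld")
}

#' @export
print.epi_ld <- function(x, ...) {
  cat("<epi_ld> n =", x$n, " pA =", signif(x$pA, 4),
      " pB =", signif(x$pB, 4), "\n")
  if (!is.null(x$r2_em)) cat("  EM:  D =", signif(x$D, 4),
                             " r2 =", signif(x$r2_em, 4), "\n")
  if (!is.null(x$r2_chm)) cat("  CHM: delta =", signif(x$delta_comp, 4),
                              " r2 =", signif(x$r2_chm, 4), "\n")
  invisible(x)
}

#' Adjacent-pair epi-LD profile of a beta matrix
#'
#' Categorizes beta values to dosages and computes epi-LD for every pair of
#' consecutive probes on the same chromosome (probes are kept in genomic
#' order by the `beta_matrix` contract, so shuffled input yields the same
#' profile). Subjects missing either probe of a pair are excluded pairwise.
#'
#' @param bm a [beta_matrix()] with at least 2 probes.
#' @param method `"both"` (default), `"em"` or `"chm"`.
#' @param uu_max,mm_min category boundaries for [beta_dosage()].
#' @return Data frame with one row per adjacent pair: `probe_a`, `probe_b`,
#'   `chrom`, `n`, `pA`, `pB`, `D`, `r2_em`, `delta_comp`, `r2_chm`,
#'   `converged`. Columns of an unselected method are `NA`.
#' @export
adjacent_ld_profile <- function(bm, method = c("both", "em", "chm"),
                                uu_max = 0.2, mm_min = 0.6) {
  method <- match.arg(method)
  stopifnot(inherits(bm, "beta_matrix"))
  if (nrow(bm$probes) < 2L) stop("need at least 2 probes")
  dos <- matrix(beta_dosage(as.vector(bm$values), uu_max, mm_min),
                nrow = nrow(bm$values))
  pr <- bm$probes
  idx <- which(pr$chrom[-nrow(pr)] == pr$chrom[-1L])
  if (length(idx) == 0L) stop("no adjacent probe pairs on a shared chromosome")
  rows <- lapply(idx, function(i) {
    g1 <- dos[, i]
    g2 <- dos[, i + 1L]
    ok <- !is.na(g1) & !is.na(g2)
    out <- data.frame(probe_a = pr$probe_id[i], probe_b = pr$probe_id[i + 1L],
                      chrom = pr$chrom[i], n = sum(ok),
                      pA = NA_real_, pB = NA_real_, D = NA_real_,
                      r2_em = NA_real_, delta_comp = NA_real_,
                      r2_chm = NA_real_, converged = NA,
                      stringsAsFactors = FALSE)
    if (sum(ok) < 2L) return(out)
    if (method %in% c("both", "em")) {
      em <- em_ld(g1[ok], g2[ok])
      out$pA <- em$pA; out$pB <- em$pB; out$D <- em$D
      out$r2_em <- em$r2_em; out$converged <- em$converged
    }
    if (method %in% c("both", "chm")) {
      ch <- chm_ld(g1[ok], g2[ok])
      out$pA <- ch$pA; out$pB <- ch$pB
      out$delta_comp <- ch$delta_comp; out$r2_chm <- ch$r2_chm
    }
    out
  })
  do.call(rbind, rows)
}

#' Assemble epi-haplotype blocks from an adjacent-LD profile
#'
#' Maximal runs of consecutive same-chromosome pairs with defined
#' `r^2 >= r2_min` become blocks (ties at the boundary are included).
#' An undefined (`NA`) `r^2` breaks a run; it is never treated as 0.
#'
#' @param profile output of [adjacent_ld_profile()].
#' @param r2_min minimum adjacent `r^2` within a block.
#' @param method which `r^2` column to use (`"em"` or `"chm"`).
#' @return List of blocks, each a list with `probes` (ordered probe ids,
#'   length >= 2), `chrom` and `min_r2`.
#' @export
build_blocks <- function(profile, r2_min = 0.8, method = c("em", "chm")) {
  method <- match.arg(method)
  if (is.null(profile) || nrow(profile) == 0L) return(list())
  r2 <- profile[[paste0("r2_", method)]]
  ok <- !is.na(r2) & r2 >= r2_min
  # a run also breaks where consecutive profile rows are not chained
  # (probe_b of row i must be probe_a of row i+1, same chrom)
  chained <- c(profile$probe_b[-nrow(profile)] == profile$probe_a[-1L] &
                 profile$chrom[-nrow(profile)] == profile$chrom[-1L], FALSE)
  blocks <- list()
  i <- 1L
  while (i <= nrow(profile)) {
    if (!ok[i]) { i <- i + 1L; next }
    j <- i
    while (j < nrow(profile) && chained[j] && ok[j + 1L]) j <- j + 1L
    probes <- c(profile$probe_a[i], profile$probe_b[i:j])
    blocks[[length(blocks) + 1L]] <-
      list(probes = probes, chrom = profile$chrom[i],
           min_r2 = min(r2[i:j]))
    i <- j + 1L
  }
  blocks
}

#' Export a square r-squared matrix for epi-LD plots
#'
#' @param profile output of [adjacent_ld_profile()].
#' @param method `"em"` or `"chm"`.
#' @return Square numeric matrix over all probes in the profile, with the
#'   adjacent-pair `r^2` on the first off-diagonal, 1 on the diagonal and
#'   `NA` elsewhere.
#' @export
ld_matrix <- function(profile, method = c("em", "chm")) {
  method <- match.arg(method)
  probes <- unique(c(profile$probe_a, profile$probe_b))
  m <- matrix(NA_real_, length(probes), length(probes),
              dimnames = list(probes, probes))
  diag(m) <- 1
  r2 <- profile[[paste0("r2_", method)]]
  for (i in seq_len(nrow(profile))) {
    a <- profile$probe_a[i]; b <- profile$probe_b[i]
    m[a, b] <- m[b, a] <- r2[i]
  }
  m
}
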