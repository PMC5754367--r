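test_that("em_ld closed-form cases", {
  # 50 (0,0) + 50 (2,2): no double-hets, perfect LD in closed form
  d <- dosages_from_counts(c("0,0" = 50, "2,2" = 50))
  em <- em_ld(d$g1, d$g2)
  expect_equal(em$pA, 0.5)
  expect_equal(em$pB, 0.5)
  expect_equal(unname(em$hap_freqs[c("UU", "MM")]), c(0.5, 0.5))
  expect_equal(em$D, 0.25)
  expect_equal(em$r2_em, 1)

  # monomorphic locus: r2 undefined, not 0
  d <- dosages_from_counts(c("2,2" = 40))
  expect_true(is.na(em_ld(d$g1, d$g2)$r2_em))
  expect_error(em_ld(2L, 2L[0]), "equal length")
  expect_error(em_ld(1L, 1L), "at least 2")
})

test_that("em_ld matches the grid-search likelihood oracle (frozen case)", {
  d <- dosages_from_counts(c("0,0" = 30, "1,1" = 40, "2,2" = 30))
  em <- em_ld(d$g1, d$g2)
  oracle <- ld_grid_oracle(d$g1, d$g2)
  # value frozen from the oracle: the MLE phases all double-hets cis
  expect_equal(oracle$r2, 1, tolerance = 1e-9)
  expect_equal(oracle$p_mm, 0.5, tolerance = 1e-9)
  expect_equal(em$r2_em, oracle$r2, tolerance = 1e-3)
})

test_that("em_ld agrees with the oracle on random tables", {
  set.seed(501)
  for (i in 1:30) {
    pA <- runif(1, 0.2, 0.8)
    pB <- runif(1, 0.2, 0.8)
    lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
    pmm <- runif(1, lo, hi)
    hf <- c(1 - pA - pB + pmm, pB - pmm, pA - pmm, pmm)
    d <- random_genotype_table(50, hf)
    em <- em_ld(d$g1, d$g2)
    oracle <- ld_grid_oracle(d$g1, d$g2)
    if (is.na(oracle$r2)) next
    expect_lte(abs(em$r2_em - oracle$r2), 1e-3)
  }
})

test_that("chm_ld composite formulas (hand-computed case)", {
  d <- dosages_from_counts(c("0,0" = 50, "2,2" = 50))
  ch <- chm_ld(d$g1, d$g2)
  expect_equal(ch$delta_comp, 0.5)
  expect_equal(ch$dA, 0.25)
  expect_equal(ch$dB, 0.25)
  expect_equal(ch$r2_chm, 1)

  d <- dosages_from_counts(c("2,2" = 30))
  expect_true(is.na(chm_ld(d$g1, d$g2)$r2_chm))
})

test_that("chm r2 vanishes for independent loci", {
  set.seed(99)
  g1 <- sample(0:2, 5000, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  g2 <- sample(0:2, 5000, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  expect_lt(chm_ld(g1, g2)$r2_chm, 0.01)
  expect_lt(em_ld(g1, g2)$r2_em, 0.01)
})

test_that("r2 is invariant to locus swap and joint M<->U relabeling", {
  set.seed(77)
  d <- random_genotype_table(80, c(0.35, 0.15, 0.1, 0.4))
  r_ab <- em_ld(d$g1, d$g2)$r2_em
  r_ba <- em_ld(d$g2, d$g1)$r2_em
  r_rel <- em_ld(2L - d$g1, 2L - d$g2)$r2_em
  expect_equal(r_ab, r_ba, tolerance = 1e-9)
  expect_equal(r_ab, r_rel, tolerance = 1e-6)
  expect_equal(chm_ld(d$g1, d$g2)$r2_chm, chm_ld(d$g2, d$g1)$r2_chm)
  expect_equal(chm_ld(d$g1, d$g2)$r2_chm,
               chm_ld(2L - d$g1, 2L - d$g2)$r2_chm)
})

test_that("adjacent_ld_profile is sort-invariant and pairs consecutively", {
  # 30 subjects; probes 1-2 perfectly concordant, probe 3 independent
  set.seed(5)
  state <- rep(c(0.05, 0.5), each = 15)
  vals <- cbind(state, state, sample(state))
  bm <- quick_bm(vals)
  prof <- adjacent_ld_profile(bm, method = "both")
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$r2_em[1], 1)
  expect_equal(prof$r2_chm[1], 1)
  expect_lt(prof$r2_em[2], 0.3)
  # shuffled probe columns give the identical profile (sorting enforced)
  shuf <- quick_bm(vals[, c(3, 1, 2)], pos = c(300, 100, 200),
                   probe_ids = c("p003", "p001", "p002"))
  expect_equal(adjacent_ld_profile(shuf, method = "both"), prof)
  # two probes -> one result
  expect_equal(nrow(adjacent_ld_profile(quick_bm(vals[, 1:2]))), 1L)
  expect_error(adjacent_ld_profile(quick_bm(vals[, 1, drop = FALSE])),
               "at least 2")
})

test_that("build_blocks forms maximal runs and breaks on undefined r2", {
  prof <- data.frame(
    probe_a = sprintf("p%d", 1:4), probe_b = sprintf("p%d", 2:5),
    chrom = "chr1", r2_em = c(1, 1, 0.1, 1))
  b <- build_blocks(prof, r2_min = 0.8)
  expect_length(b, 2L)
  expect_equal(b[[1]]$probes, c("p1", "p2", "p3"))
  expect_equal(b[[2]]$probes, c("p4", "p5"))
  # NA breaks a run and never forms a block
  prof$r2_em <- c(1, NA, 1, 1)
  b <- build_blocks(prof, r2_min = 0.8)
  expect_equal(lapply(b, `[[`, "probes"),
               list(c("p1", "p2"), c("p3", "p4", "p5")))
  prof$r2_em <- rep(NA_real_, 4)
  expect_length(build_blocks(prof), 0L)
  # boundary tie r2 == r2_min is included
  prof$r2_em <- c(0.8, 0.8, 0.8, 0.8)
  expect_length(build_blocks(prof, r2_min = 0.8), 1L)
})
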