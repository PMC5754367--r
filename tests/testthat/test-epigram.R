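test_that("build_reference enumerates CpG and non-CpG cytosines", {
  r <- build_reference("ACGT")
  expect_equal(r$cpg_positions, 1L)
  expect_equal(r$noncpg_c_positions, integer(0))

  r <- build_reference("ACCA")
  expect_equal(r$cpg_positions, integer(0))
  expect_equal(r$noncpg_c_positions, c(1L, 2L))

  expect_equal(build_reference("CGCGCG")$cpg_positions, c(0L, 2L, 4L))
  # trailing C counts as non-CpG
  expect_equal(build_reference("AAC")$noncpg_c_positions, 2L)
  # SNP on a CpG cytosine is rejected; on a non-CpG C it leaves the QC set
  expect_error(build_reference("ACGT", snp_offset = 1,
                               snp_alleles = c("G", "T")),
               "methylation-neutral")
  r <- build_reference("ACCA", snp_offset = 2, snp_alleles = c("G", "T"))
  expect_equal(r$noncpg_c_positions, 1L)
})

test_that("call_clone calls methylation, conversion rate and allele", {
  ref <- build_reference("ACGTCA")
  cl <- call_clone("ACGTTA", ref)
  expect_equal(cl$meth_calls, 1L)
  expect_equal(cl$conversion_rate, 1.0)
  expect_true(cl$passed_qc)

  cl <- call_clone("ATGTTA", ref)
  expect_equal(cl$meth_calls, 0L)
  expect_equal(cl$conversion_rate, 1.0)

  # ambiguous base at a CpG is missing
  expect_true(is.na(call_clone("ANGTTA", ref)$meth_calls))

  expect_error(call_clone("ACGT", ref), "does not match")
  expect_error(call_clone("ACGT", build_reference("ACGT")), "indeterminate")

  ref2 <- build_reference("TACGAT", snp_offset = 0,
                          snp_alleles = c("G", "T"))
  expect_error(call_clone("GACGAC", ref2), "indeterminate")
})

test_that("the conversion filter is strictly > 0.95", {
  # 20 non-CpG cytosines, 19 read as T: rate is exactly 0.95 -> fail
  ref <- build_reference(paste(rep("CA", 20), collapse = ""))
  clone <- paste(c(rep("TA", 19), "CA"), collapse = "")
  cl <- call_clone(clone, ref)
  expect_equal(cl$conversion_rate, 0.95)
  expect_false(cl$passed_qc)
  # 20 of 20 passes
  expect_true(call_clone(paste(rep("TA", 20), collapse = ""), ref)$passed_qc)
})

test_that("conversion rate ignores CpG positions (QC independence)", {
  ref <- build_reference("ACGTCATCA")  # cpg at 1, non-CpG C at 4, 7
  a <- call_clone("ACGTTATTA", ref)    # methylated CpG
  b <- call_clone("ATGTTATTA", ref)    # unmethylated CpG
  expect_equal(a$conversion_rate, b$conversion_rate)
})

test_that("raising the QC threshold never admits more clones", {
  set.seed(11)
  ref <- build_reference(paste(rep("CA", 30), collapse = ""))
  clones <- replicate(40, paste(ifelse(runif(30) < 0.93, "TA", "CA"),
                                collapse = ""))
  for (thr in c(0.90, 0.95, 0.99)) {
    n_lo <- sum(vapply(clones, function(s)
      call_clone(s, ref, conversion_min = thr)$passed_qc, logical(1)))
    n_hi <- sum(vapply(clones, function(s)
      call_clone(s, ref, conversion_min = thr + 0.005)$passed_qc, logical(1)))
    expect_lte(n_hi, n_lo)
  }
})

test_that("assemble_epigram drops QC failures and errors when all fail", {
  ref <- build_reference("ACGTCA", snp_offset = 5,
                         snp_alleles = c("G", "T"))
  pass <- lapply(1:10, function(i)
    call_clone("ACGTTG", ref, clone_id = paste0("p", i)))
  fail <- lapply(1:2, function(i)
    call_clone("ACGTCT", ref, clone_id = paste0("f", i)))  # rate 0
  expect_message(ep <- assemble_epigram(c(pass, fail), ref), "2 clone")
  expect_length(ep$clones, 10L)
  expect_equal(ep$n_dropped, 2L)
  expect_equal(unname(ep$allele_fractions["tag"]), 1.0)  # all methylated
  expect_error(suppressMessages(assemble_epigram(fail, ref)), "no clones")
})

test_that("mono-allelic epimutation calls follow the threshold rule", {
  ref <- build_reference("TACGCACA", snp_offset = 0,
                         snp_alleles = c("G", "T"))
  mk <- function(base, meth, n) {
    lapply(seq_len(n), function(i)
      call_clone(paste0(base, "A", if (meth) "CG" else "TG", "TATA"), ref))
  }
  # tag allele fully methylated, other fully unmethylated -> call G
  ep <- assemble_epigram(c(mk("G", TRUE, 10), mk("T", FALSE, 10)), ref)
  expect_equal(call_monoallelic_epimutation(ep)$call, "G")
  # mirrored -> call T
  ep <- assemble_epigram(c(mk("G", FALSE, 10), mk("T", TRUE, 10)), ref)
  expect_equal(call_monoallelic_epimutation(ep)$call, "T")
  # both unmethylated -> none
  ep <- assemble_epigram(c(mk("G", FALSE, 10), mk("T", FALSE, 10)), ref)
  expect_equal(call_monoallelic_epimutation(ep)$call, "none")
  # one allele at 0.5 -> indeterminate
  ep <- assemble_epigram(c(mk("G", TRUE, 5), mk("G", FALSE, 5),
                           mk("T", FALSE, 10)), ref)
  expect_equal(call_monoallelic_epimutation(ep)$call, "indeterminate")
  # too few clones on one allele blocks the positive call
  ep <- assemble_epigram(c(mk("G", TRUE, 2), mk("T", FALSE, 10)), ref)
  expect_equal(call_monoallelic_epimutation(ep)$call, "indeterminate")
})
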