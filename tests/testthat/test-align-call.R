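test_that("alignment of the reference to itself is the identity at full score", {
  ref <- tiny_reference()
  L <- nchar(ref$sequence)
  aln <- align_read(ref$sequence, ref)
  expect_equal(aln$score, L * 1)
  expect_identical(aln$ref_to_read, seq_len(L))
  expect_true(aln$aligned)
})

test_that("fully converted reads align as matches (bisulfite asymmetry)", {
  ref <- tiny_reference()
  converted <- gsub("C", "T", ref$sequence)
  aln <- align_read(converted, ref)
  expect_equal(aln$score, nchar(ref$sequence))
  expect_identical(aln$ref_to_read, seq_len(nchar(ref$sequence)))
  # the asymmetry is one-directional: read C opposite reference T mismatches
  expect_equal(align_read("C", "T")$score, -1)
  expect_equal(align_read("T", "C")$score, 1)
})

test_that("an internal 2-base deletion costs one length-2 gap", {
  ref <- tiny_reference()
  L <- nchar(ref$sequence)
  read <- paste0(substr(ref$sequence, 1, 7), substr(ref$sequence, 10, L))
  aln <- align_read(read, ref)
  expect_equal(aln$score, (L - 2) * 1 - 2 * 2)
  expect_equal(sum(is.na(aln$ref_to_read)), 2L)
  expect_equal(aln$score, nw_score_oracle(read, ref$sequence))
})

test_that("DP scores agree with a recursive oracle on random short sequences", {
  set.seed(101)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:9, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:9, 1), TRUE),
               collapse = "")
    expect_equal(align_read(a, b, score_floor = -Inf)$score,
                 nw_score_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("read profiles follow the calling conventions", {
  ref <- prepare_reference(tiny_reference())

  # perfectly converted, fully methylated read
  rd <- tiny_read(meth = c(1, 1, 1), allele = "A")
  prof <- call_read_profile(align_read(rd, ref), rd, ref, "r1")
  expect_equal(prof$n_meth_cpgs, 3L)
  expect_equal(prof$conversion_rate, 1.0)
  expect_equal(prof$allele, "A")
  expect_equal(prof$meth_fraction, 1.0)

  # unconverted QC cytosine drives the conversion rate down
  rd2 <- tiny_read(meth = c(0, 1, 0), convert_qc_site = FALSE)
  prof2 <- call_read_profile(align_read(rd2, ref), rd2, ref, "r2")
  expect_equal(prof2$conversion_rate, 0.0)
  expect_equal(prof2$n_meth_cpgs, 1L)

  # allele calling: G at the variant is G, anything else undetermined
  rdg <- tiny_read(allele = "G")
  expect_equal(call_read_profile(align_read(rdg, ref), rdg, ref)$allele, "G")
  rdc <- tiny_read(allele = "C")
  expect_equal(call_read_profile(align_read(rdc, ref), rdc, ref)$allele,
               "undetermined")

  # a gap at a CpG yields a missing call, excluded from the fraction
  rd3 <- tiny_read(meth = c(1, 1, 0))
  aln <- align_read(rd3, ref)
  aln$ref_to_read[ref$cpg_positions[2]] <- NA_integer_  # gapped CpG
  pd <- call_read_profile(aln, rd3, ref)
  expect_equal(pd$n_called_cpgs, 2L)
  expect_equal(pd$meth_fraction, 0.5)
})

test_that("batch calling equals per-read calling and matches simulation truth", {
  ref <- prepare_reference(builtin_amplicon_references()$region2)
  p <- derive_mixture_preset(18.24, 2.30, n_cpgs = 25)
  sim <- simulate_dbs_reads(ref, p, p, 200, conversion_failure = 0,
                            seq_error = 0, seed = 21)
  called <- call_reads(sim$reads, ref)

  # with error-free chemistry every call equals the generator's truth
  expect_true(all(called$profiles$conversion_rate == 1))
  expect_identical(called$profiles$n_meth_cpgs,
                   sim$truth$n_meth_cpgs[match(called$profiles$read_id,
                                               sim$truth$read_id)])
  expect_identical(called$profiles$allele, sim$truth$allele)

  # batch path agrees with the single-read path
  for (i in c(1L, 57L, 400L)) {
    rd <- sim$reads[i]
    prof <- call_read_profile(align_read(rd, ref), rd, ref, names(rd))
    expect_equal(called$profiles$n_meth_cpgs[i], prof$n_meth_cpgs)
    expect_equal(called$profiles$conversion_rate[i], prof$conversion_rate)
    expect_equal(called$profiles$allele[i], prof$allele)
  }
})

test_that("the QC filter applies the strict >95% conversion rule", {
  # a read with exactly 1 unconverted non-CpG cytosine of 20 sits exactly at
  # 0.95 and must be rejected by the strict filter
  profiles <- data.frame(
    read_id = sprintf("r%d", 1:4),
    allele = c("A", "G", "A", "A"),
    n_called_cpgs = c(10L, 10L, 10L, 10L),
    n_meth_cpgs = 0L, meth_fraction = 0,
    n_noncpg_c_sites = 20L,
    n_converted = c(20L, 19L, 18L, 20L),
    conversion_rate = c(1, 19 / 20, 18 / 20, 1),
    score = 100, aligned = c(TRUE, TRUE, TRUE, TRUE))
  flt <- filter_reads(profiles, n_cpgs = 10L)
  expect_identical(unname(flt$passed), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(flt$tally[["low_conversion"]], 2L)
  expect_equal(flt$profiles$rejection_reason[2], "low_conversion")
})

test_that("rejection tallies partition the input", {
  ref <- prepare_reference(builtin_amplicon_references()$region1)
  p <- derive_mixture_preset(7.92, 0.32, n_cpgs = 38)
  sim <- simulate_dbs_reads(ref, p, p, 500, conversion_failure = 0.05,
                            seq_error = 0.01, seed = 8)
  called <- call_reads(sim$reads, ref)
  flt <- filter_reads(called$profiles, n_cpgs = 38L)
  expect_equal(sum(flt$tally), nrow(called$profiles))
  expect_equal(flt$tally[["passed"]], sum(flt$passed))
  # undetermined alleles are tallied separately, never passed
  und <- flt$profiles$allele == "undetermined"
  expect_true(all(!flt$passed[und]))

  # all-undetermined input: everything lands in that tally bucket
  prof_und <- called$profiles
  prof_und$allele <- "undetermined"
  flt2 <- filter_reads(prof_und, n_cpgs = 38L)
  expect_equal(flt2$tally[["passed"]], 0L)
  expect_gt(flt2$tally[["undetermined_allele"]], 0L)

  # empty input is a zeroed tally, not an error
  flt3 <- filter_reads(called$profiles[0, ], n_cpgs = 38L)
  expect_true(all(flt3$tally == 0L))
})
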