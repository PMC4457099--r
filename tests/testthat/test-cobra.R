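test_that("bisulfite_convert protects methylated CpGs only", {
  expect_equal(bisulfite_convert(
    methylated_sequence("ACGT", 2, "methylated")), "ACGT")
  expect_equal(bisulfite_convert(
    methylated_sequence("ACGT", 2, "unmethylated")), "ATGT")
  # non-CpG Cs convert even next to a protected CpG
  expect_equal(bisulfite_convert(
    methylated_sequence("CCGAC", 2, "methylated")), "TCGAT")
})

test_that("bisulfite_convert agrees with a position-wise oracle", {
  set.seed(5)
  for (i in 1:20) {
    ms <- random_methylated_sequence()
    expect_equal(bisulfite_convert(ms),
                 oracle_convert(ms$seq, ms$cpg_positions, ms$methyl_states))
  }
})

test_that("conversion is identity on C-free sequences", {
  ms <- methylated_sequence("ATGGTTA", integer(0), character(0))
  expect_equal(bisulfite_convert(ms), "ATGGTTA")
})

test_that("methylated_sequence validates CpG positions", {
  expect_error(methylated_sequence("AAGT", 2, "methylated"), "not the C")
  expect_error(methylated_sequence("ACGT", c(2, 2),
                                   c("methylated", "methylated")),
               "duplicate")
  expect_error(methylated_sequence("ACNT", integer(0), character(0)),
               "outside A/C/G/T")
})

test_that("digest_sequence finds sites, cuts, and conserves length", {
  d <- digest_sequence("AAAA", "BstUI")
  expect_length(d$cut_positions, 0)
  expect_equal(d$fragment_lengths, 4L)
  expect_equal(d$call, "unmethylated")

  # site created by conversion of a non-CpG C
  d2 <- digest_sequence("TCGAT", "TaqI")
  expect_equal(d2$cut_positions, 1L)
  expect_equal(d2$call, "methylated")
  expect_equal(sum(d2$fragment_lengths), 5L)

  d3 <- digest_sequence("ACGCGT", "BstUI")
  expect_equal(d3$fragment_lengths, c(3L, 3L))
  expect_equal(d3$call, "methylated")

  # overlapping sites are all counted: CGCGCG has CGCG at 1 and 3
  d4 <- digest_sequence("CGCGCG", "BstUI")
  expect_equal(d4$cut_positions, c(2L, 4L))
  expect_equal(sum(d4$fragment_lengths), 6L)

  expect_error(digest_sequence("", "BstUI"), "empty")
})

test_that("fragment lengths always sum to the amplicon length", {
  set.seed(9)
  for (i in 1:50) {
    ms <- random_methylated_sequence(sample(20:120, 1))
    conv <- bisulfite_convert(ms)
    for (e in c("BstUI", "TaqI")) {
      d <- digest_sequence(conv, e)
      expect_equal(sum(d$fragment_lengths), nchar(conv))
      # cut positions match a substring-scan oracle
      site <- if (e == "BstUI") "CGCG" else "TCGA"
      off <- if (e == "BstUI") 2L else 1L
      expect_equal(d$cut_positions,
                   sort(unique(oracle_sites(conv, site) - 1L + off)))
    }
  }
})

test_that("fully unmethylated alleles never retain a CG, so BstUI never cuts", {
  set.seed(13)
  for (i in 1:50) {
    ms <- random_methylated_sequence(60)
    ms$methyl_states[] <- "unmethylated"
    conv <- bisulfite_convert(ms)
    expect_false(grepl("CG", conv, fixed = TRUE))
    expect_equal(digest_sequence(conv, "BstUI")$call, "unmethylated")
  }
})

test_that("cobra_assay calls methylated iff any enzyme cuts", {
  # fully methylated allele containing CGCG
  ms <- simulate_promoter(sim_config(seed = 1), mi = 1)
  res <- cobra_assay(ms)
  expect_equal(res$call, "methylated")
  expect_equal(res$digests$BstUI$call, "methylated")

  # fully methylated allele agrees with a site-enumeration oracle on the
  # original amplicon: methylation preserves every C, so CoBRA must cut
  # exactly when the untreated amplicon contains a recognition site whose
  # CpGs are all retained
  set.seed(21)
  for (i in 1:20) {
    ms <- random_methylated_sequence(70)
    ms$methyl_states[] <- "methylated"
    conv <- bisulfite_convert(ms)
    any_site <- length(oracle_sites(conv, "CGCG")) +
      length(oracle_sites(conv, "TCGA")) > 0
    expect_equal(cobra_assay(ms)$call,
                 if (any_site) "methylated" else "unmethylated")
  }
})

test_that("cobra_pool thresholds the allele cut fraction", {
  cfg <- sim_config(seed = 2)
  hot <- replicate(8, simulate_promoter(cfg, mi = 1), simplify = FALSE)
  cold <- lapply(hot, function(a) {
    a$methyl_states[] <- "unmethylated"; a
  })
  expect_equal(cobra_pool(hot)$call, "methylated")
  expect_equal(cobra_pool(cold)$call, "unmethylated")
  # 2 of 8 cut = 0.25 is not strictly above the default threshold
  mix <- c(hot[1:2], cold[1:6])
  res <- cobra_pool(mix)
  expect_equal(res$cut_fraction_observed, 0.25)
  expect_equal(res$call, "unmethylated")
  expect_equal(cobra_pool(mix, cut_fraction = 0.2)$call, "methylated")
})
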