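make_calls <- function(gene = "G1", cohort = "met", calls) {
  call_table(sample_id = sprintf("%s_s%03d", cohort, seq_along(calls)),
             cohort = cohort, gene = gene, call = calls)
}

test_that("gene_frequencies excludes failed calls from both counts", {
  calls <- make_calls(calls = c(rep("methylated", 22), rep("unmethylated", 8)))
  fr <- gene_frequencies(calls)
  expect_equal(fr$n_evaluable, 30L)
  expect_equal(fr$n_methylated, 22L)
  expect_equal(fr$frequency, 100 * 22 / 30, tolerance = 1e-12)

  with_failed <- make_calls(calls = c(rep("methylated", 10),
                                      rep("unmethylated", 5),
                                      rep("failed", 5)))
  fr2 <- gene_frequencies(with_failed)
  expect_equal(fr2$n_evaluable, 15L)
  expect_equal(fr2$frequency, 100 * 10 / 15, tolerance = 1e-12)

  all_failed <- make_calls(calls = rep("failed", 4))
  fr3 <- gene_frequencies(all_failed)
  expect_true(fr3$flagged)
  expect_equal(fr3$n_evaluable, 0L)
  expect_true(is.na(fr3$frequency))

  none <- make_calls(cohort = "primary", calls = rep("unmethylated", 40))
  expect_equal(gene_frequencies(none)$frequency, 0)
})

test_that("call_table rejects duplicate sample/gene records and bad calls", {
  expect_error(call_table(c("s1", "s1"), "c", c("G", "G"),
                          c("methylated", "methylated")), "duplicate")
  expect_error(call_table("s1", "c", "G", "meth"), "invalid")
})

test_that("apply_filters uses inclusive cutoffs on both cohorts", {
  fr <- rbind(
    gene_frequency_table(c("A", "B", "C"), "met", c(50, 49.9, 80)),
    gene_frequency_table(c("A", "B", "C"), "prim", c(45, 10, 45.1))
  )
  flt <- apply_filters(fr, "met", "prim")
  expect_setequal(flt$frequent_in_met, c("A", "C"))
  expect_equal(flt$selected, "A")   # boundary 50/45 is selected

  # missing cohort -> warning + exclusion
  fr2 <- rbind(fr, gene_frequency_table("D", "met", 90))
  expect_warning(flt2 <- apply_filters(fr2, "met", "prim"), "missing one")
  expect_false("D" %in% flt2$frequent_in_met)

  # relaxing the infrequent cutoff never removes a selected gene
  flt3 <- apply_filters(fr, "met", "prim", infrequent_cutoff = 60)
  expect_true(all(flt$selected %in% flt3$selected))
})

test_that("differential_test reproduces hand-enumerated exact p-values", {
  # (5/5 vs 0/5): 2 * C(5,5) C(5,0) / C(10,5) = 2/252
  expect_equal(differential_test(5, 5, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(differential_test(3, 10, 3, 10), 1)
  expect_lt(differential_test(17, 30, 0, 40), 1e-4)
  expect_error(differential_test(0, 0, 1, 5), "positive")
  expect_error(differential_test(6, 5, 0, 5), "counts")
})

test_that("differential_test is symmetric and agrees with fisher.test", {
  set.seed(19)
  for (i in 1:50) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
    p <- differential_test(a, n1, c_, n2)
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(p, differential_test(c_, n2, a, n1), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(a, n1 - a, c_, n2 - c_), 2))$p.value
    expect_equal(p, ft, tolerance = 1e-9)
  }
})

test_that("differential_results joins frequencies, p-values and selection", {
  calls <- rbind(
    as.data.frame(make_calls("G1", "met",
                             c(rep("methylated", 20), rep("unmethylated", 10)))),
    as.data.frame(make_calls("G1", "prim",
                             c(rep("methylated", 2), rep("unmethylated", 38)))),
    as.data.frame(make_calls("G2", "met", rep("unmethylated", 30))),
    as.data.frame(make_calls("G2", "prim", rep("unmethylated", 40)))
  )
  ct <- call_table(calls$sample_id, calls$cohort, calls$gene, calls$call)
  fr <- gene_frequencies(ct)
  res <- differential_results(fr, "met", "prim")
  expect_equal(res$gene, c("G1", "G2"))
  expect_true(res$selected[1])
  expect_false(res$selected[2])
  expect_equal(res$p_value[1],
               differential_test(20, 30, 2, 40), tolerance = 1e-12)
  res_bh <- differential_results(fr, "met", "prim", adjust = "BH")
  expect_true("p_adjusted" %in% names(res_bh))
  expect_equal(res_bh$p_adjusted,
               stats::p.adjust(res_bh$p_value, "BH"))
})
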