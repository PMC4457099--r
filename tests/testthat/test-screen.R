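make_annotation <- function() {
  probe_annotation(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_symbols = list("A", "A", c("A", "B"), character(0)),
    tss_groups = list("TSS200", "Body", c("TSS1500", "Body"), character(0)),
    island_relation = c("Island", "OpenSea", "Island", "Shore")
  )
}

test_that("filter_promoter_probes keeps exactly the accepted TSS groups", {
  ann <- make_annotation()
  expect_equal(filter_promoter_probes(ann), c("p1", "p3"))

  # 10 probes, 3 with TSS1500, 7 with Body -> the 3
  ann10 <- probe_annotation(
    sprintf("q%02d", 1:10),
    gene_symbols = as.list(sprintf("G%d", 1:10)),
    tss_groups = as.list(c(rep("TSS1500", 3), rep("Body", 7))),
    island_relation = rep("Island", 10)
  )
  expect_setequal(filter_promoter_probes(ann10), c("q01", "q02", "q03"))

  # unknown token -> warning, treated as non-promoter
  annx <- probe_annotation("x1", list("G"), list("Promoter?"), "Island")
  expect_warning(res <- filter_promoter_probes(annx), "unknown TSS group")
  expect_length(res, 0)
})

test_that("prevalence_fraction counts inclusively over non-missing values", {
  expect_equal(prevalence_fraction(c(0.1, 0.2, 0.9, 0.2), 0.25, "at_most"),
               0.75)
  expect_equal(prevalence_fraction(rep(0, 20), 0.25, "at_most"), 1)
  expect_equal(prevalence_fraction(c(0.6, 0.59, NA, 0.7), 0.60, "at_least"),
               2 / 3)
  expect_error(prevalence_fraction(c(NA_real_, NA_real_), 0.25, "at_most"),
               "unevaluable")
})

test_that("screen_cohort applies the prevalence rule per mode", {
  mk <- function(vals) {
    m <- matrix(vals, nrow = 1,
                dimnames = list("p1", sprintf("s%02d", seq_along(vals))))
    beta_matrix(m, "c")
  }
  expect_equal(screen_cohort(mk(rep(0.1, 20)), "unmethylated"), "p1",
               ignore_attr = TRUE)
  # 9/20 at 0.9 < 50 % -> fails the methylated screen
  expect_length(screen_cohort(mk(c(rep(0.9, 9), rep(0.1, 11))),
                              "methylated"), 0)
  # exactly 10/20 passes (inclusive)
  expect_equal(screen_cohort(mk(c(rep(0.9, 10), rep(0.1, 10))),
                             "methylated"), "p1", ignore_attr = TRUE)
  # <50 % informative samples -> unevaluable
  sparse <- mk(c(rep(0.1, 9), rep(NA, 11)))
  out <- screen_cohort(sparse, "unmethylated")
  expect_length(out, 0)
  expect_equal(attr(out, "unevaluable"), "p1")
})

test_that("screen_cohort matches the nested-loop oracle on random matrices", {
  set.seed(42)
  for (rep in 1:10) {
    v <- random_beta_values(30, 25)
    bm <- beta_matrix(v, "c")
    for (mode in c("unmethylated", "methylated"))
      expect_setequal(as.character(screen_cohort(bm, mode)),
                      oracle_screen(v, mode))
  }
})

test_that("screening is monotone in its thresholds", {
  set.seed(7)
  v <- random_beta_values(40, 20)
  bm <- beta_matrix(v, "c")
  base_u <- screen_cohort(bm, "unmethylated", screen_config())
  wider <- screen_cohort(bm, "unmethylated",
                         screen_config(unmeth_beta_max = 0.4))
  expect_true(all(base_u %in% wider))
  base_m <- screen_cohort(bm, "methylated",
                          screen_config(meth_sample_frac = 0.3))
  stricter <- screen_cohort(bm, "methylated",
                            screen_config(meth_sample_frac = 0.7))
  expect_true(all(stricter %in% base_m))
})

test_that("screen result is invariant to probe and sample order", {
  set.seed(11)
  v <- random_beta_values(25, 15)
  ann <- probe_annotation(rownames(v), as.list(rownames(v)),
                          as.list(rep("TSS200", 25)), rep("Island", 25))
  r1 <- run_screen(beta_matrix(v, "a"),
                   beta_matrix(1 - v, "b"), ann)
  perm <- v[sample(nrow(v)), sample(ncol(v))]
  r2 <- run_screen(beta_matrix(perm, "a"),
                   beta_matrix(1 - perm, "b"), ann)
  expect_equal(r1$candidate_genes, r2$candidate_genes)
  expect_equal(r1$intersect_probes, r2$intersect_probes)
})

test_that("intersect_and_collapse maps probes to genes and gates on islands", {
  ann <- make_annotation()
  # p3 -> genes A and B, both islands
  res <- intersect_and_collapse(c("p1", "p3"), c("p3", "p2"), ann)
  expect_equal(res$intersect_probes, "p3")
  expect_setequal(res$candidate_genes, c("A", "B"))
  expect_length(res$dropped_no_island, 0)

  # OpenSea-only support -> dropped
  res2 <- intersect_and_collapse("p2", "p2", ann)
  expect_equal(res2$dropped_no_island, "A")
  expect_length(res2$candidate_genes, 0)
  expect_length(intersect(res2$candidate_genes, res2$dropped_no_island), 0)

  # island gating off keeps the gene
  res3 <- intersect_and_collapse("p2", "p2", ann,
                                 screen_config(require_island = FALSE))
  expect_equal(res3$candidate_genes, "A")

  # structural invariants
  expect_true(all(res$intersect_probes %in% res$unmeth_probes))
  expect_true(all(res$intersect_probes %in% res$meth_probes))

  expect_error(intersect_and_collapse("p9", "p9", ann), "absent")
})

test_that("a gene with island and non-island support is kept", {
  ann <- probe_annotation(c("p1", "p2"), list("A", "A"),
                          list("TSS200", "TSS200"),
                          c("OpenSea", "Island"))
  res <- intersect_and_collapse(c("p1", "p2"), c("p1", "p2"), ann)
  expect_equal(res$candidate_genes, "A")
})

test_that("planted probes are recovered exactly under complete separation", {
  cfg <- sim_config(seed = 3, complete_separation = TRUE)
  ann <- simulate_annotation(cfg)
  breast <- simulate_beta_matrix(cfg, "breast", annotation = ann)
  lung <- simulate_beta_matrix(cfg, "lung", annotation = ann)
  res <- run_screen(breast$matrix, lung$matrix, ann)
  planted <- breast$truth$probe_id[breast$truth$planted]
  expect_setequal(res$intersect_probes, planted)
})
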