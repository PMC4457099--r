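#' Run the whole pipeline on simulated data
#'
#' Composes every stage on data from the synthetic generator: the
#' two-cohort array screen on simulated beta matrices, cohort frequency
#' filtering with Fisher exact differential tests on the simulated
#' validation cohorts, and matched-pair timing classification. Returns the
#' per-stage results together with the generator's ground truth, so
#' parameter recovery can be scored.
#'
#' @param cfg a [pipeline_config][read_pipeline_config] or a [sim_config]
#'   (screen/filter defaults then apply).
#' @return list: `screen` (a `screen_result`), `screen_truth`,
#'   `frequencies`, `differential`, `timing`, `cohort_truth`.
#' @export
run_all <- function(cfg = sim_config()) {
  if (inherits(cfg, "sim_config"))
    cfg <- as_pipeline_config(list(sim = unclass(cfg)))
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- cfg$sim

  ann <- simulate_annotation(sim)
  breast <- simulate_beta_matrix(sim, "breast", annotation = ann)
  lung <- simulate_beta_matrix(sim, "lung", annotation = ann)
  screen <- run_screen(breast$matrix, lung$matrix, ann, cfg$screen)

  paired <- simulate_paired_cohort(sim)
  freqs <- gene_frequencies(paired$calls)
  diff <- differential_results(freqs, "metastasis", "primary",
                               cfg$filters$frequent_cutoff,
                               cfg$filters$infrequent_cutoff)
  timing <- timing_table(paired$pairs)

  list(screen = screen,
       screen_truth = attr(ann, "sim_truth"),
       frequencies = freqs,
       differential = diff,
       timing = timing,
       cohort_truth = paired$truth)
}

#' Score planted-parameter recovery of one pipeline run
#'
#' Compares a [run_all] result with its recorded truth: the screen stage
#' must recover exactly the planted probes, the differential stage exactly
#' the planted (`early`/`late`) genes, and the timing stage the planted
#' timing label of every recovered planted gene.
#'
#' @param res result of [run_all].
#' @return list of logicals: `screen_exact`, `selection_exact`,
#'   `timing_exact`, `all`.
#' @export
score_recovery <- function(res) {
  planted_probes <- res$screen_truth$probe_id[res$screen_truth$planted]
  screen_exact <- setequal(res$screen$intersect_probes, planted_probes)

  truth <- res$cohort_truth
  planted_genes <- truth$gene[truth$timing != "none"]
  selection_exact <- setequal(res$differential$gene[res$differential$selected],
                              planted_genes)

  tm <- res$timing
  lab <- tm$gene_timing[match(planted_genes, tm$gene)]
  timing_exact <- identical(unname(lab),
                            truth$timing[match(planted_genes, truth$gene)])
  list(screen_exact = screen_exact,
       selection_exact = selection_exact,
       timing_exact = timing_exact,
       all = screen_exact && selection_exact && timing_exact)
}

#' Write a complete synthetic fixture set
#'
#' Materialises every interchange format the pipeline reads: probe
#' annotation CSV, per-cohort beta TSVs, amplicon FASTA + methylation-state
#' sidecar, clone-state CSVs, a call CSV, a matched-pairs CSV, and a ground
#' truth JSON.
#'
#' @param cfg a [sim_config].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
simulate_fixtures <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  ann <- simulate_annotation(cfg)
  breast <- simulate_beta_matrix(cfg, "breast", annotation = ann)
  lung <- simulate_beta_matrix(cfg, "lung", annotation = ann)
  write_annotation(ann, p("annotation.csv"))
  write_beta_matrix(breast$matrix, p("breast.tsv"))
  write_beta_matrix(lung$matrix, p("lung.tsv"))

  amplicons <- list(
    amp_methylated = simulate_promoter(cfg, mi = 0.9),
    amp_unmethylated = simulate_promoter(cfg, mi = 0.1)
  )
  write_amplicons(amplicons, p("amplicons.fa"), p("states.csv"))

  clone_dir <- p("clones")
  dir.create(clone_dir, showWarnings = FALSE)
  write_clone_matrix(simulate_clones(cfg, 0.8, gene = "GENE", sample = "hi"),
                     file.path(clone_dir, "GENE_hi.csv"))
  write_clone_matrix(simulate_clones(cfg, 0.1, gene = "GENE", sample = "lo"),
                     file.path(clone_dir, "GENE_lo.csv"))

  paired <- simulate_paired_cohort(cfg)
  utils::write.csv(as.data.frame(paired$calls), p("calls.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(paired$pairs), p("pairs.csv"),
                   row.names = FALSE, quote = FALSE, na = "")

  truth <- list(
    seed = cfg$seed,
    planted_probes = attr(ann, "sim_truth")$probe_id[
      attr(ann, "sim_truth")$planted],
    gene_timing = stats::setNames(as.list(paired$truth$timing),
                                  paired$truth$gene)
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(c(annotation = p("annotation.csv"), breast = p("breast.tsv"),
              lung = p("lung.tsv"), fasta = p("amplicons.fa"),
              states = p("states.csv"), clones = clone_dir,
              calls = p("calls.csv"), pairs = p("pairs.csv"),
              truth = p("truth.json")))
}
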