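#' Simulation configuration
#'
#' The generator emulates the published study design at its stated scale:
#' an array stage with 20 samples per discovery cohort, a CoBRA validation
#' stage with 30 metastases and 40 independent primary tumours, 10 matched
#' pairs per gene, 10 sequenced clones per amplicon, and a 2 % call-flip
#' noise that jointly models assay failure and biological heterogeneity.
#' Beta values are drawn from a two-component Beta mixture
#' (Beta(2,8) unmethylated / Beta(8,2) methylated) that straddles the 0.25
#' and 0.60 screen thresholds with realistic overlap.
#'
#' @param seed integer seed; all generators are deterministic given it.
#' @param n_probes number of array probes (default 500).
#' @param n_samples_per_cohort named integer vector, samples per cohort.
#' @param planted_genes named character vector: gene -> timing
#'   (`early`/`late`/`none`).
#' @param n_background_genes number of additional unmethylated (`none`)
#'   genes (default 17, for a 20-gene panel).
#' @param beta_unmeth_params,beta_meth_params shape pairs of the Beta
#'   mixture components.
#' @param complete_separation if `TRUE`, draw betas uniformly from
#'   `[0, 0.15]` / `[0.8, 1]` instead (no component overlap).
#' @param clone_count,cpg_count clone-matrix dimensions.
#' @param conversion_error_rate incomplete bisulfite conversion rate.
#' @param call_noise probability that a simulated categorical call is
#'   flipped (default 0.02).
#' @param n_met_samples,n_primary_samples,n_pairs cohort sizes of the
#'   validation stage.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 500L,
                       n_samples_per_cohort = c(breast = 20L, lung = 20L),
                       planted_genes = c(GENE_L1 = "late", GENE_L2 = "late",
                                         GENE_E1 = "early"),
                       n_background_genes = 17L,
                       beta_unmeth_params = c(2, 8),
                       beta_meth_params = c(8, 2),
                       complete_separation = FALSE,
                       clone_count = 10L,
                       cpg_count = 20L,
                       conversion_error_rate = 0,
                       call_noise = 0.02,
                       n_met_samples = 30L,
                       n_primary_samples = 40L,
                       n_pairs = 10L) {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_probes >= 1, all(n_samples_per_cohort >= 1),
            all(planted_genes %in% c("early", "late", "none")),
            call_noise >= 0, call_noise <= 1)
  structure(list(seed = as.integer(seed), n_probes = as.integer(n_probes),
                 n_samples_per_cohort = n_samples_per_cohort,
                 planted_genes = planted_genes,
                 n_background_genes = as.integer(n_background_genes),
                 beta_unmeth_params = beta_unmeth_params,
                 beta_meth_params = beta_meth_params,
                 complete_separation = isTRUE(complete_separation),
                 clone_count = as.integer(clone_count),
                 cpg_count = as.integer(cpg_count),
                 conversion_error_rate = conversion_error_rate,
                 call_noise = call_noise,
                 n_met_samples = as.integer(n_met_samples),
                 n_primary_samples = as.integer(n_primary_samples),
                 n_pairs = as.integer(n_pairs)),
            class = "sim_config")
}

# Seed the RNG reproducibly for one named generator stage. Offsets keep the
# stages independent while remaining a pure function of cfg$seed.
stage_seed <- function(cfg, stage) {
  offset <- c(beta_breast = 11L, beta_lung = 12L, beta = 13L,
              promoter = 29L, clones = 41L, paired = 53L)[[stage]]
  set.seed((cfg$seed * 101L + offset) %% .Machine$integer.max)
}

rbeta_state <- function(n, state, cfg) {
  if (cfg$complete_separation) {
    switch(state,
           methylated = stats::runif(n, 0.8, 1),
           unmethylated = stats::runif(n, 0, 0.15),
           intermediate = stats::runif(n, 0.3, 0.55))
  } else {
    p <- switch(state,
                methylated = cfg$beta_meth_params,
                unmethylated = cfg$beta_unmeth_params,
                intermediate = c(5, 5))
    stats::rbeta(n, p[1], p[2])
  }
}

#' Simulate a cohort beta matrix with recorded truth
#'
#' Each probe carries a true per-cohort state: planted differential probes
#' are fully unmethylated in the reference (`breast`) cohort and fully
#' methylated in the comparison (`lung`) cohort; background probes are
#' assigned a state pair that never mimics the planted combination, so the
#' planted set is exactly the set a perfect screen should recover. Per
#' sample, the beta value is drawn from the component of the probe's
#' state; `intermediate` probes (hemimethylation-like) draw from a
#' mid-range Beta(5,5) component that clears both screen thresholds.
#'
#' @param cfg a [sim_config].
#' @param cohort `"breast"` or `"lung"` (or any label in
#'   `cfg$n_samples_per_cohort`).
#' @param n_planted number of planted differential probes (default 8, one
#'   per array-stage hit).
#' @param annotation optional [probe_annotation] from
#'   [simulate_annotation]; generated if missing.
#' @return list: `matrix` (a [beta_matrix]), `truth` (data.frame
#'   `probe_id`, `state`, `planted`), `annotation`.
#' @export
simulate_beta_matrix <- function(cfg, cohort, n_planted = 8L,
                                 annotation = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(annotation))
    annotation <- simulate_annotation(cfg, n_planted)
  if (!cohort %in% names(cfg$n_samples_per_cohort))
    stopf("cohort %s not in sim config", cohort)
  n_samples <- cfg$n_samples_per_cohort[[cohort]]
  stage_seed(cfg, if (cohort %in% c("breast", "lung"))
    paste0("beta_", cohort) else "beta")

  truth <- attr(annotation, "sim_truth")
  state <- truth[[paste0("state_", cohort)]] %||% truth$state_breast
  vals <- matrix(NA_real_, nrow = cfg$n_probes, ncol = n_samples,
                 dimnames = list(truth$probe_id,
                                 sprintf("%s_s%02d", cohort,
                                         seq_len(n_samples))))
  for (i in seq_len(cfg$n_probes))
    vals[i, ] <- rbeta_state(n_samples, state[i], cfg)
  list(matrix = beta_matrix(vals, cohort),
       truth = data.frame(probe_id = truth$probe_id, state = state,
                          planted = truth$planted, stringsAsFactors = FALSE),
       annotation = annotation)
}

#' Simulate a 450K-style probe annotation with planted differential probes
#'
#' Planted probes are promoter (TSS200/TSS1500), island-associated, and
#' unmethylated-in-breast / methylated-in-lung; background probes mix
#' promoter and body locations, island relations, and non-differential
#' state pairs.
#'
#' @param cfg a [sim_config].
#' @param n_planted number of planted probes.
#' @return A [probe_annotation] with a `sim_truth` attribute.
#' @export
simulate_annotation <- function(cfg, n_planted = 8L) {
  stopifnot(inherits(cfg, "sim_config"), n_planted <= cfg$n_probes)
  set.seed((cfg$seed * 101L + 7L) %% .Machine$integer.max)
  n <- cfg$n_probes
  probe_id <- sprintf("cg%08d", seq_len(n))
  planted <- seq_len(n) <= n_planted
  planted_genes <- sprintf("PLANT%d", 1 + (seq_len(n_planted) - 1) %/% 2)

  gene_pool <- sprintf("BG%04d", seq_len(max(20, n %/% 5)))
  gene <- character(n)
  gene[planted] <- planted_genes
  gene[!planted] <- sample(gene_pool, n - n_planted, replace = TRUE)

  tss <- character(n)
  tss[planted] <- sample(c("TSS200", "TSS1500"), n_planted, replace = TRUE)
  tss[!planted] <- sample(c("TSS200", "TSS1500", "Body", "5'UTR", "3'UTR"),
                          n - n_planted, replace = TRUE,
                          prob = c(0.2, 0.2, 0.4, 0.1, 0.1))
  island <- character(n)
  island[planted] <- "Island"
  island[!planted] <- sample(ISLAND_LEVELS, n - n_planted, replace = TRUE,
                             prob = c(0.35, 0.25, 0.15, 0.25))

  # background state pairs: anything but (unmethylated breast, methylated
  # lung), which is reserved for planted probes
  pair_pool <- list(c("unmethylated", "unmethylated"),
                    c("methylated", "methylated"),
                    c("methylated", "unmethylated"),
                    c("intermediate", "intermediate"),
                    c("intermediate", "unmethylated"),
                    c("unmethylated", "intermediate"))
  pick <- sample(length(pair_pool), n - n_planted, replace = TRUE)
  state_breast <- character(n); state_lung <- character(n)
  state_breast[planted] <- "unmethylated"; state_lung[planted] <- "methylated"
  state_breast[!planted] <- vapply(pick, function(i) pair_pool[[i]][1],
                                   character(1))
  state_lung[!planted] <- vapply(pick, function(i) pair_pool[[i]][2],
                                 character(1))

  ann <- probe_annotation(probe_id, as.list(gene), as.list(tss), island)
  attr(ann, "sim_truth") <- data.frame(
    probe_id = probe_id, planted = planted, gene = gene,
    state_breast = state_breast, state_lung = state_lung,
    stringsAsFactors = FALSE)
  ann
}

#' Simulate a promoter amplicon with methylation states
#'
#' Builds a GC-rich island-like amplicon guaranteed to contain at least one
#' `CGCG` (BstUI site when methylated) and one `CCGA` (a TaqI-site
#' precursor: bisulfite conversion of its leading non-CpG C yields `TCGA`
#' when the CpG is methylated). CpG states are drawn i.i.d. Bernoulli at
#' the requested allele methylation level.
#'
#' @param cfg a [sim_config].
#' @param mi allele methylation probability in `[0, 1]`.
#' @param length_bp approximate amplicon length (default 160).
#' @return A [methylated_sequence].
#' @export
simulate_promoter <- function(cfg, mi = 1, length_bp = 160L) {
  stopifnot(inherits(cfg, "sim_config"), mi >= 0, mi <= 1)
  stage_seed(cfg, "promoter")
  # GC-rich background without accidental loss of the guaranteed motifs
  bases <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE,
                  prob = c(0.15, 0.35, 0.35, 0.15))
  seq <- paste(bases, collapse = "")
  # plant the motifs at fixed interior offsets
  insert_at <- function(s, motif, at) {
    paste0(substr(s, 1, at - 1), motif,
           substr(s, at + nchar(motif), nchar(s)))
  }
  seq <- insert_at(seq, "CGCG", 21L)
  seq <- insert_at(seq, "ACCGAA", 61L)  # CCGA precursor, flanked to keep it
  cpg <- find_cpg_sites(seq)
  states <- ifelse(stats::runif(length(cpg)) < mi,
                   "methylated", "unmethylated")
  if (mi == 1) states[] <- "methylated"
  if (mi == 0) states[] <- "unmethylated"
  methylated_sequence(seq, cpg, states)
}

#' Simulate a clone bisulfite-sequencing matrix
#'
#' States are i.i.d. Bernoulli(`true_mi`) per clone x CpG; a missing rate
#' masks states at random.
#'
#' @param cfg a [sim_config].
#' @param true_mi true per-CpG methylation probability in `[0, 1]`.
#' @param missing_rate probability a state is unreadable (default 0).
#' @param gene,sample identifiers for the matrix.
#' @return A [clone_matrix] (errors if every state is masked).
#' @export
simulate_clones <- function(cfg, true_mi, missing_rate = 0,
                            gene = "gene", sample = "sample") {
  stopifnot(inherits(cfg, "sim_config"), true_mi >= 0, true_mi <= 1,
            missing_rate >= 0, missing_rate <= 1)
  stage_seed(cfg, "clones")
  n <- cfg$clone_count * cfg$cpg_count
  states <- matrix(as.integer(stats::runif(n) < true_mi),
                   nrow = cfg$clone_count, ncol = cfg$cpg_count)
  if (missing_rate > 0)
    states[stats::runif(n) < missing_rate] <- NA_integer_
  clone_matrix(states, gene = gene, sample = sample)
}

flip_calls <- function(calls, noise) {
  if (noise <= 0) return(calls)
  flip <- stats::runif(length(calls)) < noise
  ifelse(flip, ifelse(calls == "methylated", "unmethylated", "methylated"),
         calls)
}

#' Simulate validation cohorts and matched pairs with planted timing
#'
#' Generates (i) a [call_table] for a metastasis cohort and an independent
#' primary cohort, and (ii) matched primary/metastasis pairs, under the
#' planted timing model: `early` and `late` genes are methylated in every
#' metastasis; `early` genes are additionally methylated in the matched
#' primaries (the tumours that metastasised), while the independent
#' non-metastasising primary cohort stays unmethylated for all planted
#' genes; `none` genes are unmethylated everywhere. Each call is then
#' flipped independently with probability `cfg$call_noise`.
#'
#' @param cfg a [sim_config].
#' @return list: `calls` (a [call_table]), `pairs` (a [matched_pairs]
#'   table), `truth` (data.frame `gene`, `timing`).
#' @export
simulate_paired_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  stage_seed(cfg, "paired")
  timing <- c(cfg$planted_genes,
              stats::setNames(rep("none", cfg$n_background_genes),
                              sprintf("NONE%02d", seq_len(cfg$n_background_genes))))
  genes <- names(timing)

  records <- list(); k <- 0
  add <- function(sample, cohort, gene, call) {
    k <<- k + 1
    records[[k]] <<- data.frame(sample_id = sample, cohort = cohort,
                                gene = gene, call = call,
                                stringsAsFactors = FALSE)
  }
  for (g in genes) {
    met_call <- if (timing[[g]] == "none") "unmethylated" else "methylated"
    add(sprintf("met_%02d", seq_len(cfg$n_met_samples)), "metastasis", g,
        flip_calls(rep(met_call, cfg$n_met_samples), cfg$call_noise))
    add(sprintf("prim_%02d", seq_len(cfg$n_primary_samples)), "primary", g,
        flip_calls(rep("unmethylated", cfg$n_primary_samples),
                   cfg$call_noise))
  }
  calls_df <- do.call(rbind, records)
  calls <- call_table(calls_df$sample_id, calls_df$cohort, calls_df$gene,
                      calls_df$call)

  pair_rows <- lapply(genes, function(g) {
    met <- if (timing[[g]] == "none") "unmethylated" else "methylated"
    prim <- if (timing[[g]] == "early") "methylated" else "unmethylated"
    data.frame(patient_id = sprintf("pt_%02d", seq_len(cfg$n_pairs)),
               gene = g,
               primary_call = flip_calls(rep(prim, cfg$n_pairs),
                                         cfg$call_noise),
               metastasis_call = flip_calls(rep(met, cfg$n_pairs),
                                            cfg$call_noise),
               stringsAsFactors = FALSE)
  })
  pr <- do.call(rbind, pair_rows)
  pairs <- matched_pairs(pr$patient_id, pr$gene, pr$primary_call,
                         pr$metastasis_call)
  list(calls = calls, pairs = pairs,
       truth = data.frame(gene = genes, timing = unname(timing),
                          stringsAsFactors = FALSE))
}
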