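#' Screen configuration
#'
#' Thresholds for the two-cohort beta-value prevalence screen. Defaults
#' encode the published design: a probe is called infrequently methylated in
#' the reference (breast) cohort when beta <= 0.25 in at least 75 % of
#' samples, and frequently methylated in the comparison (lung) cohort when
#' beta >= 0.60 in at least 50 % of samples. All comparisons are inclusive.
#'
#' @param unmeth_beta_max beta threshold for the unmethylated state (default
#'   0.25).
#' @param unmeth_sample_frac minimum fraction of samples at or below
#'   `unmeth_beta_max` (default 0.75).
#' @param meth_beta_min beta threshold for the methylated state (default
#'   0.60).
#' @param meth_sample_frac minimum fraction of samples at or above
#'   `meth_beta_min` (default 0.50).
#' @param accepted_tss_groups TSS-relation groups counted as promoter
#'   (default `TSS200`, `TSS1500`).
#' @param require_island drop candidate genes whose supporting probes are
#'   all outside CpG islands (default `TRUE`).
#' @param min_informative_frac minimum fraction of non-missing beta values
#'   for a probe to be evaluable in a cohort (default 0.5).
#' @return A `screen_config` list.
#' @export
screen_config <- function(unmeth_beta_max = 0.25,
                          unmeth_sample_frac = 0.75,
                          meth_beta_min = 0.60,
                          meth_sample_frac = 0.50,
                          accepted_tss_groups = c("TSS200", "TSS1500"),
                          require_island = TRUE,
                          min_informative_frac = 0.5) {
  stopifnot(unmeth_beta_max >= 0, unmeth_beta_max < meth_beta_min,
            meth_beta_min <= 1,
            unmeth_sample_frac > 0, unmeth_sample_frac <= 1,
            meth_sample_frac > 0, meth_sample_frac <= 1,
            min_informative_frac >= 0, min_informative_frac <= 1)
  structure(list(unmeth_beta_max = unmeth_beta_max,
                 unmeth_sample_frac = unmeth_sample_frac,
                 meth_beta_min = meth_beta_min,
                 meth_sample_frac = meth_sample_frac,
                 accepted_tss_groups = as.character(accepted_tss_groups),
                 require_island = isTRUE(require_island),
                 min_informative_frac = min_informative_frac),
            class = "screen_config")
}

#' Select promoter-associated probes
#'
#' Keeps probes with at least one TSS-relation group in
#' `config$accepted_tss_groups` (by default within 1500 bp of a transcription
#' start site). Probes carrying TSS-group tokens outside the standard
#' manifest vocabulary trigger a warning and are treated as non-promoter.
#'
#' @param annotation a [probe_annotation].
#' @param config a [screen_config].
#' @return character vector of promoter probe ids (input order).
#' @export
filter_promoter_probes <- function(annotation, config = screen_config()) {
  stopifnot(inherits(annotation, "probe_annotation"), nrow(annotation) > 0)
  vocab <- union(methscreen_tss_vocabulary(), config$accepted_tss_groups)
  unknown <- setdiff(unique(unlist(annotation$tss_groups)), vocab)
  if (length(unknown) > 0)
    warnf("unknown TSS group token(s) treated as non-promoter: %s",
          paste(unknown, collapse = ", "))
  keep <- vapply(annotation$tss_groups,
                 function(g) any(g %in% config$accepted_tss_groups),
                 logical(1))
  annotation$probe_id[keep]
}

#' Prevalence of a beta state along one probe row
#'
#' Fraction of non-missing samples whose beta value satisfies the inclusive
#' comparison; missing values are excluded from numerator and denominator.
#'
#' @param beta_row numeric vector of beta values (may contain `NA`).
#' @param threshold beta threshold.
#' @param direction `"at_most"` (unmethylated state) or `"at_least"`
#'   (methylated state).
#' @return fraction in `[0, 1]`.
#' @export
prevalence_fraction <- function(beta_row,
                                threshold,
                                direction = c("at_most", "at_least")) {
  direction <- match.arg(direction)
  obs <- beta_row[!is.na(beta_row)]
  if (length(obs) == 0)
    stopf("probe unevaluable: all beta values missing")
  hits <- if (direction == "at_most") sum(obs <= threshold)
          else sum(obs >= threshold)
  hits / length(obs)
}

#' Screen one cohort for prevalent beta states
#'
#' In `unmethylated` mode returns probes with
#' `prevalence_fraction(row, unmeth_beta_max, at_most) >= unmeth_sample_frac`;
#' `methylated` mode uses `meth_beta_min` / `at_least` / `meth_sample_frac`.
#' Probes with fewer than `min_informative_frac` non-missing samples are
#' excluded as unevaluable and returned in the `"unevaluable"` attribute.
#'
#' @param bm a [beta_matrix].
#' @param mode `"unmethylated"` or `"methylated"`.
#' @param config a [screen_config].
#' @return character vector of passing probe ids, with attribute
#'   `unevaluable`.
#' @export
screen_cohort <- function(bm, mode = c("unmethylated", "methylated"),
                          config = screen_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(bm, "beta_matrix"))
  m <- unclass(bm)
  n_obs <- rowSums(!is.na(m))
  evaluable <- n_obs >= config$min_informative_frac * ncol(m) & n_obs > 0
  if (mode == "unmethylated") {
    hits <- rowSums(m <= config$unmeth_beta_max, na.rm = TRUE)
    frac_needed <- config$unmeth_sample_frac
  } else {
    hits <- rowSums(m >= config$meth_beta_min, na.rm = TRUE)
    frac_needed <- config$meth_sample_frac
  }
  pass <- evaluable & (hits / pmax(n_obs, 1L)) >= frac_needed
  out <- rownames(m)[pass]
  attr(out, "unevaluable") <- rownames(m)[!evaluable]
  out
}

#' Intersect cohort screens and collapse to candidate genes
#'
#' Intersects the unmethylated-in-reference and methylated-in-comparison
#' probe sets, maps surviving probes to genes (a probe annotating several
#' genes contributes to all of them), and, when `config$require_island`,
#' moves genes whose supporting probes all lie outside CpG islands into
#' `dropped_no_island`. Stage counts are recorded for the promoter-filtered
#' pipeline and, for audit, for the unfiltered prevalence sets.
#'
#' @param unmeth character vector of probe ids passing the unmethylated
#'   screen.
#' @param meth character vector of probe ids passing the methylated screen.
#' @param annotation a [probe_annotation] covering all probes in both sets.
#' @param config a [screen_config].
#' @return A `screen_result` list: `stage_counts`, `unmeth_probes`,
#'   `meth_probes`, `intersect_probes`, `candidate_genes`,
#'   `dropped_no_island`, `probe_genes`.
#' @export
intersect_and_collapse <- function(unmeth, meth, annotation,
                                   config = screen_config()) {
  stopifnot(inherits(annotation, "probe_annotation"))
  unmeth <- sort(unique(as.character(unmeth)))
  meth <- sort(unique(as.character(meth)))
  absent <- setdiff(c(unmeth, meth), annotation$probe_id)
  if (length(absent) > 0)
    stopf("probe(s) absent from annotation: %s", paste(absent, collapse = ", "))
  inter <- intersect(unmeth, meth)

  idx <- match(inter, annotation$probe_id)
  probe_genes <- annotation$gene_symbols[idx]
  names(probe_genes) <- inter
  island <- annotation$island_relation[idx]

  genes <- sort(unique(unlist(probe_genes)))
  gene_has_island <- vapply(genes, function(g) {
    supporting <- vapply(probe_genes, function(gs) g %in% gs, logical(1))
    any(island[supporting] == "Island")
  }, logical(1))

  if (config$require_island) {
    candidates <- genes[gene_has_island]
    dropped <- genes[!gene_has_island]
  } else {
    candidates <- genes
    dropped <- character(0)
  }

  stage_counts <- c(
    n_unmeth_probes = length(unmeth),
    n_meth_probes = length(meth),
    n_intersect_probes = length(inter),
    n_genes = length(genes),
    n_candidate_genes = length(candidates),
    n_dropped_no_island = length(dropped)
  )
  structure(list(stage_counts = stage_counts,
                 unmeth_probes = unmeth,
                 meth_probes = meth,
                 intersect_probes = inter,
                 candidate_genes = candidates,
                 dropped_no_island = dropped,
                 probe_genes = probe_genes),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-22s %d\n", nm, x$stage_counts[[nm]]))
  cat("  candidates:", paste(x$candidate_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full two-cohort probe screen
#'
#' Applies the promoter filter to the annotation, screens the reference
#' cohort for unmethylated probes and the comparison cohort for methylated
#' probes (restricted to promoter probes), then intersects and collapses to
#' genes. Stage counts additionally record prevalence-pass counts before
#' promoter filtering, since published pipelines differ in the order of the
#' two filters.
#'
#' @param unmeth_bm reference-cohort [beta_matrix] (screened for the
#'   unmethylated state).
#' @param meth_bm comparison-cohort [beta_matrix] (screened for the
#'   methylated state).
#' @param annotation a [probe_annotation].
#' @param config a [screen_config].
#' @return A `screen_result` (see [intersect_and_collapse]).
#' @export
run_screen <- function(unmeth_bm, meth_bm, annotation,
                       config = screen_config()) {
  promoter <- filter_promoter_probes(annotation, config)
  unmeth_all <- screen_cohort(unmeth_bm, "unmethylated", config)
  meth_all <- screen_cohort(meth_bm, "methylated", config)
  unmeth <- intersect(unmeth_all, promoter)
  meth <- intersect(meth_all, promoter)
  res <- intersect_and_collapse(unmeth, meth, annotation, config)
  res$stage_counts <- c(
    n_probes_annotation = nrow(annotation),
    n_promoter_probes = length(promoter),
    n_unmeth_probes_unfiltered = length(unmeth_all),
    n_meth_probes_unfiltered = length(meth_all),
    res$stage_counts
  )
  res
}
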