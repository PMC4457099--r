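#' Read amplicons with their methylation states
#'
#' Amplicon sequences come from a FASTA file; per-CpG methylation states
#' from a sidecar CSV with header `record_id, cpg_positions, states`, where
#' `cpg_positions` are 0-based `;`-separated indices of CpG cytosines and
#' `states` a parallel `;`-separated list of `M`/`U`. Every sidecar record
#' must match a FASTA record.
#'
#' @param fasta_path FASTA file of amplicons.
#' @param states_path sidecar CSV.
#' @return named list of [methylated_sequence] objects.
#' @export
read_amplicons <- function(fasta_path, states_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  df <- utils::read.csv(states_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("record_id", "cpg_positions", "states")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stopf("states file %s is missing required column(s): %s",
          states_path, paste(miss, collapse = ", "))
  absent <- setdiff(df$record_id, names(seqs))
  if (length(absent) > 0)
    stopf("states record(s) missing from FASTA: %s",
          paste(absent, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    pos0 <- as.integer(split_field(df$cpg_positions[i]))
    st <- split_field(df$states[i])
    bad <- setdiff(unique(st), c("M", "U"))
    if (length(bad) > 0)
      stopf("invalid state token(s) for %s: %s", df$record_id[i],
            paste(bad, collapse = ", "))
    methylated_sequence(
      as.character(seqs[[df$record_id[i]]]),
      cpg_positions = pos0 + 1L,  # 0-based on disk -> 1-based in R
      methyl_states = ifelse(st == "M", "methylated", "unmethylated"))
  })
  names(out) <- df$record_id
  out
}

#' Write amplicons and their methylation states
#' @param amplicons named list of [methylated_sequence] objects.
#' @param fasta_path,states_path output paths.
#' @return invisibly, the two paths.
#' @export
write_amplicons <- function(amplicons, fasta_path, states_path) {
  stopifnot(length(amplicons) > 0, !is.null(names(amplicons)))
  seqs <- Biostrings::DNAStringSet(vapply(amplicons, `[[`, character(1),
                                          "seq"))
  Biostrings::writeXStringSet(seqs, fasta_path)
  df <- data.frame(
    record_id = names(amplicons),
    cpg_positions = vapply(amplicons, function(a)
      join_field(a$cpg_positions - 1L), character(1)),  # 0-based on disk
    states = vapply(amplicons, function(a)
      join_field(ifelse(a$methyl_states == "methylated", "M", "U")),
      character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, states_path, row.names = FALSE, quote = FALSE)
  invisible(c(fasta = fasta_path, states = states_path))
}

#' Write a JSON analysis report
#'
#' Serialises any pipeline result together with the parameters used, the
#' seed (if any) and the package version, so a run is auditable.
#'
#' @param results a `screen_result`, data.frame, or plain list.
#' @param path output JSON path.
#' @param params optional list of parameters to record.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, params = NULL, seed = NULL) {
  payload <- list(
    tool = "methscreen",
    version = as.character(utils::packageVersion("methscreen")),
    seed = seed,
    params = params,
    results = unclass_deep(results)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  # named atomic vectors (stage counts etc.) serialize as JSON objects
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  if (!is.null(attr(x, "class")) && !is.function(x)) return(unclass(x))
  x
}

#' Read / write a pipeline configuration
#'
#' The configuration is a YAML mapping with optional blocks `screen`
#' (arguments of [screen_config]), `sim` (arguments of [sim_config]),
#' `filters` (`frequent_cutoff`, `infrequent_cutoff`), `mi`
#' (`methylated_min`, `unmethylated_max`) and `cobra` (`cut_fraction`,
#' `error_rate`). Unset values take package defaults; the round-trip
#' through [write_pipeline_config] is lossless.
#'
#' @param path YAML path.
#' @return a `pipeline_config` list with all blocks populated.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path) %||% list()
  as_pipeline_config(raw)
}

as_pipeline_config <- function(raw) {
  cfg <- list(
    screen = do.call(screen_config, raw$screen %||% list()),
    sim = do.call(sim_config, normalize_sim_args(raw$sim %||% list())),
    filters = utils::modifyList(list(frequent_cutoff = 50,
                                     infrequent_cutoff = 45),
                                raw$filters %||% list()),
    mi = utils::modifyList(list(methylated_min = 60, unmethylated_max = 40),
                           raw$mi %||% list()),
    cobra = utils::modifyList(list(cut_fraction = 0.25, error_rate = 0),
                              raw$cobra %||% list())
  )
  class(cfg) <- "pipeline_config"
  cfg
}

normalize_sim_args <- function(x) {
  # YAML maps come back as lists; sim_config wants named vectors for these
  for (f in c("n_samples_per_cohort", "planted_genes"))
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  for (f in c("beta_unmeth_params", "beta_meth_params"))
    if (!is.null(x[[f]])) x[[f]] <- as.numeric(unlist(x[[f]]))
  x
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  # named vectors become YAML maps (yaml drops names of atomic vectors)
  yaml::write_yaml(lapply(unclass(cfg), function(b)
    lapply(unclass(b), function(v)
      if (is.atomic(v) && !is.null(names(v))) as.list(v) else v)), path)
  invisible(path)
}

#' Bundled cohort methylation-frequency table
#'
#' CoBRA methylation frequencies (percent) of the 21 genes frequently
#' methylated in a breast-to-brain metastasis (BBM) cohort, together with
#' the corresponding frequencies in an independent primary breast-tumour
#' cohort, as published for this study panel (denominators were not
#' reported, so counts are `NA`). Cohort labels are `bbm` and `primary`.
#'
#' @return A `gene_frequency` data.frame (two rows per gene).
#' @export
bbm_frequency_table <- function() {
  path <- system.file("extdata", "bbm_cohort_frequencies.csv",
                      package = "methscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rbind(
    gene_frequency_table(df$gene, "bbm", df$freq_bbm),
    gene_frequency_table(df$gene, "primary", df$freq_primary)
  )
}

#' Bundled matched-pair call table
#'
#' Matched primary/metastasis promoter methylation calls for the three
#' differentially methylated genes (BNC1, CCDC8, GALNT9), encoding the
#' published per-patient gel calls: pairs where a locus failed to amplify
#' in the FFPE primary are recorded as `failed`.
#'
#' @return A [matched_pairs] table.
#' @export
bbm_matched_pairs <- function() {
  path <- system.file("extdata", "bbm_matched_pairs.csv",
                      package = "methscreen", mustWork = TRUE)
  read_matched_pairs(path)
}
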