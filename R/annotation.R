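#' Probe annotation tables
#'
#' A probe annotation set is a manifest-style table describing 450K-type
#' array probes: the probe identifier, the gene(s) the probe annotates, the
#' probe's relation to the transcription start site of each gene (one TSS
#' group per gene, parallel to `gene_symbols`), and the probe's relation to a
#' CpG island.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param gene_symbols list of character vectors, one per probe (may be
#'   empty for unannotated probes).
#' @param tss_groups list of character vectors parallel to `gene_symbols`;
#'   element `i` gives the TSS relation of the probe to gene `i`. Standard
#'   vocabulary: `r paste(methscreen_tss_vocabulary(), collapse = ", ")`.
#' @param island_relation character vector; one of `Island`, `Shore`,
#'   `Shelf`, `OpenSea` (case-insensitive on input, normalized).
#'
#' @return A `probe_annotation` object: a data.frame with list-columns
#'   `gene_symbols` and `tss_groups`.
#' @export
probe_annotation <- function(probe_id, gene_symbols, tss_groups,
                             island_relation) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id))
    stopf("duplicate probe_id: %s",
          paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  if (!is.list(gene_symbols)) gene_symbols <- as.list(gene_symbols)
  if (!is.list(tss_groups)) tss_groups <- as.list(tss_groups)
  if (length(gene_symbols) != length(probe_id) ||
      length(tss_groups) != length(probe_id))
    stopf("gene_symbols and tss_groups must have one entry per probe")
  ok <- mapply(function(g, t) length(g) == length(t),
               gene_symbols, tss_groups)
  if (!all(ok))
    stopf("probe(s) with mismatched gene_symbols/tss_groups lengths: %s",
          paste(probe_id[!ok], collapse = ", "))
  island_relation <- normalize_island_relation(island_relation, probe_id)

  out <- data.frame(probe_id = probe_id, stringsAsFactors = FALSE)
  out$gene_symbols <- lapply(gene_symbols, as.character)
  out$tss_groups <- lapply(tss_groups, as.character)
  out$island_relation <- island_relation
  class(out) <- c("probe_annotation", "data.frame")
  out
}

ISLAND_LEVELS <- c("Island", "Shore", "Shelf", "OpenSea")

normalize_island_relation <- function(x, probe_id) {
  x <- as.character(x)
  idx <- match(tolower(x), tolower(ISLAND_LEVELS))
  if (anyNA(idx))
    stopf("invalid island_relation for probe(s) %s (allowed: %s)",
          paste(probe_id[is.na(idx)], collapse = ", "),
          paste(ISLAND_LEVELS, collapse = ", "))
  ISLAND_LEVELS[idx]
}

#' Standard TSS-relation vocabulary used by 450K-style manifests
#' @return character vector of recognized TSS-group tokens.
#' @export
methscreen_tss_vocabulary <- function() {
  c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")
}

#' Read a probe annotation CSV
#'
#' Expected header: `probe_id, gene_symbols, tss_groups, island_relation`,
#' where `gene_symbols` and `tss_groups` are `;`-separated parallel lists.
#'
#' @param path path to a CSV file.
#' @return A [probe_annotation] object.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("probe_id", "gene_symbols", "tss_groups", "island_relation")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stopf("annotation file %s is missing required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  probe_annotation(
    probe_id = df$probe_id,
    gene_symbols = lapply(df$gene_symbols, split_field),
    tss_groups = lapply(df$tss_groups, split_field),
    island_relation = df$island_relation
  )
}

#' Write a probe annotation CSV
#' @param annotation a [probe_annotation] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "probe_annotation"))
  df <- data.frame(
    probe_id = annotation$probe_id,
    gene_symbols = vapply(annotation$gene_symbols, join_field, character(1)),
    tss_groups = vapply(annotation$tss_groups, join_field, character(1)),
    island_relation = annotation$island_relation,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
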