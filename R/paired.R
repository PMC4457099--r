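#' Matched primary/metastasis call pairs
#'
#' One row per patient x gene: the promoter methylation call in the primary
#' breast tumour and in the brain metastasis of the same patient, plus an
#' optional adjacent-normal call (reported but never used by the timing
#' rule).
#'
#' @param patient_id,gene character vectors.
#' @param primary_call,metastasis_call calls in
#'   `methylated`/`unmethylated`/`failed`.
#' @param normal_call optional adjacent-normal calls (`NA` when absent).
#' @return A `matched_pairs` data.frame.
#' @export
matched_pairs <- function(patient_id, gene, primary_call, metastasis_call,
                          normal_call = NA_character_) {
  df <- data.frame(patient_id = as.character(patient_id),
                   gene = as.character(gene),
                   primary_call = as.character(primary_call),
                   metastasis_call = as.character(metastasis_call),
                   normal_call = as.character(normal_call),
                   stringsAsFactors = FALSE)
  check_calls(df$primary_call, "primary")
  check_calls(df$metastasis_call, "metastasis")
  check_calls(df$normal_call[!is.na(df$normal_call)], "normal")
  key <- paste(df$patient_id, df$gene)
  if (anyDuplicated(key))
    stopf("duplicate (patient_id, gene) pair(s): %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  class(df) <- c("matched_pairs", "data.frame")
  df
}

#' Read a matched-pairs CSV
#'
#' Header: `patient_id, gene, primary_call, metastasis_call` and optional
#' `normal_call`.
#'
#' @param path CSV path.
#' @return A [matched_pairs] table.
#' @export
read_matched_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("patient_id", "gene", "primary_call", "metastasis_call")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stopf("pairs file %s is missing required column(s): %s",
          path, paste(miss, collapse = ", "))
  nc <- if ("normal_call" %in% names(df)) {
    x <- df$normal_call; x[!nzchar(x)] <- NA_character_; x
  } else NA_character_
  matched_pairs(df$patient_id, df$gene, df$primary_call,
                df$metastasis_call, nc)
}

#' Classify one matched pair
#'
#' `both` if primary and metastasis are methylated, `met_only` /
#' `primary_only` if exactly one is, `neither` if none, `unevaluable` if
#' either call failed.
#'
#' @param primary_call,metastasis_call single calls (or equal-length
#'   vectors; the function is vectorised).
#' @return character vector of categories.
#' @export
classify_pair <- function(primary_call, metastasis_call) {
  check_calls(primary_call, "primary")
  check_calls(metastasis_call, "metastasis")
  p <- primary_call == "methylated"
  m <- metastasis_call == "methylated"
  out <- ifelse(p & m, "both",
         ifelse(!p & m, "met_only",
         ifelse(p & !m, "primary_only", "neither")))
  out[primary_call == "failed" | metastasis_call == "failed"] <- "unevaluable"
  out
}

#' Epimutation timing from matched pairs
#'
#' For one gene, counts pair categories over evaluable pairs and labels the
#' gene's epimutation timing. Among pairs whose metastasis is methylated,
#' let `f` be the fraction whose primary is also methylated: the gene is an
#' *early* event if `f >= early_frac` (methylation was already present in
#' the originating primary), otherwise a *late* event if
#' `f <= 1 - late_frac` (methylation confined to the metastasis), otherwise
#' `mixed`. With the 0.5/0.5 defaults `early` takes the boundary `f = 0.5`.
#' Genes with no methylated metastasis are labelled `none`.
#'
#' @param pairs a [matched_pairs] table.
#' @param gene gene to summarise; default when the table holds one gene.
#' @param early_frac,late_frac thresholds in `[0, 1]` (defaults 0.5).
#' @return A `timing_summary` list: `gene`, `n_pairs_evaluable`, `n_both`,
#'   `n_met_only`, `n_primary_only`, `n_neither`, `n_unevaluable`,
#'   `primary_given_met_frac`, `gene_timing`.
#' @export
summarize_timing <- function(pairs, gene = NULL,
                             early_frac = 0.5, late_frac = 0.5) {
  stopifnot(inherits(pairs, "matched_pairs"))
  if (is.null(gene)) {
    gene <- unique(pairs$gene)
    if (length(gene) != 1)
      stopf("pairs table holds several genes; pass `gene`")
  }
  sub <- pairs[pairs$gene == gene, ]
  if (nrow(sub) == 0) stopf("no pairs for gene %s", gene)
  cat_ <- classify_pair(sub$primary_call, sub$metastasis_call)
  n <- c(both = sum(cat_ == "both"),
         met_only = sum(cat_ == "met_only"),
         primary_only = sum(cat_ == "primary_only"),
         neither = sum(cat_ == "neither"),
         unevaluable = sum(cat_ == "unevaluable"))
  n_eval <- sum(n[c("both", "met_only", "primary_only", "neither")])
  if (n_eval == 0) stopf("no evaluable pairs for gene %s", gene)
  n_met_meth <- n[["both"]] + n[["met_only"]]
  if (n_met_meth == 0) {
    f <- NA_real_
    timing <- "none"
  } else {
    f <- n[["both"]] / n_met_meth
    timing <- if (f >= early_frac) "early"
              else if (f <= 1 - late_frac) "late"
              else "mixed"
  }
  structure(list(gene = gene,
                 n_pairs_evaluable = n_eval,
                 n_both = n[["both"]],
                 n_met_only = n[["met_only"]],
                 n_primary_only = n[["primary_only"]],
                 n_neither = n[["neither"]],
                 n_unevaluable = n[["unevaluable"]],
                 primary_given_met_frac = f,
                 gene_timing = timing),
            class = "timing_summary")
}

#' Timing summaries for every gene in a pairs table
#' @param pairs a [matched_pairs] table.
#' @inheritParams summarize_timing
#' @return data.frame, one row per gene, columns as in [summarize_timing].
#' @export
timing_table <- function(pairs, early_frac = 0.5, late_frac = 0.5) {
  genes <- sort(unique(pairs$gene))
  rows <- lapply(genes, function(g) {
    s <- summarize_timing(pairs, g, early_frac, late_frac)
    as.data.frame(unclass(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
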