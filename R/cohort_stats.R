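#' Per-sample methylation call tables
#'
#' Long-format table of categorical promoter methylation calls: one row per
#' sample x gene, with the cohort the sample belongs to. Calls are
#' `methylated`, `unmethylated` or `failed` (assay did not amplify).
#'
#' @param sample_id,cohort,gene,call character vectors of equal length.
#' @return A `call_table` data.frame.
#' @export
call_table <- function(sample_id, cohort, gene, call) {
  df <- data.frame(sample_id = as.character(sample_id),
                   cohort = as.character(cohort),
                   gene = as.character(gene),
                   call = as.character(call),
                   stringsAsFactors = FALSE)
  check_calls(df$call, "methylation")
  key <- paste(df$sample_id, df$gene, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (sample_id, gene) record(s): %s",
          paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  class(df) <- c("call_table", "data.frame")
  df
}

#' Read a call CSV (`sample_id, cohort, gene, call`)
#' @param path CSV path.
#' @return A [call_table].
#' @export
read_call_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("sample_id", "cohort", "gene", "call")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stopf("call file %s is missing required column(s): %s",
          path, paste(miss, collapse = ", "))
  call_table(df$sample_id, df$cohort, df$gene, df$call)
}

#' Per-gene, per-cohort methylation frequencies
#'
#' Failed calls are excluded from numerator and denominator. A gene with no
#' evaluable sample in a cohort is kept with `n_evaluable = 0`, an `NA`
#' frequency and `flagged = TRUE`. Output is ordered by gene then cohort.
#'
#' @param table a [call_table].
#' @return A `gene_frequency` data.frame: `gene`, `cohort`, `n_evaluable`,
#'   `n_methylated`, `frequency` (percentage), `flagged`.
#' @export
gene_frequencies <- function(table) {
  stopifnot(inherits(table, "call_table"), nrow(table) > 0)
  grid <- unique(table[, c("gene", "cohort")])
  grid <- grid[order(grid$gene, grid$cohort), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- table[table$gene == grid$gene[i] & table$cohort == grid$cohort[i], ]
    ev <- sub$call != "failed"
    n_ev <- sum(ev)
    n_meth <- sum(sub$call == "methylated")
    gene_frequency_record(grid$gene[i], grid$cohort[i], n_ev, n_meth)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_frequency", "data.frame")
  out
}

gene_frequency_record <- function(gene, cohort, n_evaluable, n_methylated) {
  data.frame(gene = gene, cohort = cohort,
             n_evaluable = as.integer(n_evaluable),
             n_methylated = as.integer(n_methylated),
             frequency = if (n_evaluable > 0)
               100 * n_methylated / n_evaluable else NA_real_,
             flagged = n_evaluable == 0,
             stringsAsFactors = FALSE)
}

#' Build a gene-frequency table from printed percentages
#'
#' Some published frequency tables report percentages without denominators;
#' this constructor admits such tables directly (counts unknown, `NA`).
#'
#' @param gene,cohort character vectors.
#' @param frequency numeric percentages in `[0, 100]`.
#' @param n_evaluable,n_methylated optional integer counts.
#' @return A `gene_frequency` data.frame.
#' @export
gene_frequency_table <- function(gene, cohort, frequency,
                                 n_evaluable = NA_integer_,
                                 n_methylated = NA_integer_) {
  stopifnot(all(is.na(frequency) | (frequency >= 0 & frequency <= 100)))
  out <- data.frame(gene = as.character(gene), cohort = as.character(cohort),
                    n_evaluable = as.integer(n_evaluable),
                    n_methylated = as.integer(n_methylated),
                    frequency = as.numeric(frequency),
                    flagged = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("gene_frequency", "data.frame")
  out
}

#' Frequent / infrequent cohort filters
#'
#' Applies the published two-stage gene filter: a gene is *frequently
#' methylated* when its metastasis-cohort frequency is at or above
#' `frequent_cutoff` (default 50 %), and *selected* when additionally its
#' primary-cohort frequency is at or below `infrequent_cutoff` (default
#' 45 %). Both comparisons are inclusive and use unrounded frequencies.
#' Genes missing either cohort are excluded with a warning.
#'
#' @param freqs a `gene_frequency` data.frame covering both cohorts.
#' @param met_cohort,primary_cohort cohort labels.
#' @param frequent_cutoff,infrequent_cutoff percentages.
#' @return list: `frequent_in_met` (character), `selected` (character),
#'   `table` (per-gene data.frame with both frequencies and flags).
#' @export
apply_filters <- function(freqs, met_cohort, primary_cohort,
                          frequent_cutoff = 50, infrequent_cutoff = 45) {
  stopifnot(inherits(freqs, "data.frame"))
  met <- freqs[freqs$cohort == met_cohort & !freqs$flagged, ]
  prim <- freqs[freqs$cohort == primary_cohort & !freqs$flagged, ]
  genes <- sort(unique(c(met$gene, prim$gene)))
  incomplete <- genes[!(genes %in% met$gene & genes %in% prim$gene)]
  if (length(incomplete) > 0)
    warnf("gene(s) missing one cohort, excluded: %s",
          paste(incomplete, collapse = ", "))
  genes <- setdiff(genes, incomplete)
  tab <- data.frame(
    gene = genes,
    freq_met = met$frequency[match(genes, met$gene)],
    freq_primary = prim$frequency[match(genes, prim$gene)],
    stringsAsFactors = FALSE
  )
  tab$frequent_in_met <- tab$freq_met >= frequent_cutoff
  tab$selected <- tab$frequent_in_met & tab$freq_primary <= infrequent_cutoff
  list(frequent_in_met = tab$gene[tab$frequent_in_met],
       selected = tab$gene[tab$selected],
       table = tab)
}

#' Two-sided Fisher exact test for a 2x2 methylation table
#'
#' Exact hypergeometric test of equal methylation frequency in two cohorts:
#' the two-sided p-value sums the probabilities of every table (with the
#' observed margins) whose probability does not exceed that of the observed
#' table. No continuity or large-sample approximation is used.
#'
#' @param n_met_methylated,n_met_total methylated count and evaluable total
#'   in the metastasis cohort.
#' @param n_prim_methylated,n_prim_total likewise for the primary cohort.
#' @return two-sided p-value.
#' @export
differential_test <- function(n_met_methylated, n_met_total,
                              n_prim_methylated, n_prim_total) {
  a <- as.integer(n_met_methylated); n1 <- as.integer(n_met_total)
  c_ <- as.integer(n_prim_methylated); n2 <- as.integer(n_prim_total)
  if (n1 <= 0 || n2 <= 0) stopf("cohort totals must be positive")
  if (a < 0 || c_ < 0 || a > n1 || c_ > n2)
    stopf("counts must satisfy 0 <= methylated <= total in each cohort")
  m <- a + c_                      # methylated margin
  support <- max(0L, m - n2):min(m, n1)
  d <- stats::dhyper(support, n1, n2, m)
  # include all tables at most as probable as observed, with a relative
  # tolerance so exact ties survive floating-point evaluation
  p_obs <- d[match(a, support)]
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Differential methylation over a gene-frequency table
#'
#' Runs [differential_test] per gene on evaluable counts and applies the
#' frequency filters. Genes without counts (printed-percentage tables) get
#' an `NA` p-value but are still filtered on frequency.
#'
#' @inheritParams apply_filters
#' @param adjust `"none"` (default, as in the original design) or `"BH"`
#'   for Benjamini-Hochberg adjusted p-values in column `p_adjusted`.
#' @return data.frame: `gene`, `freq_met`, `freq_primary`, `p_value`,
#'   (`p_adjusted`), `selected`.
#' @export
differential_results <- function(freqs, met_cohort, primary_cohort,
                                 frequent_cutoff = 50, infrequent_cutoff = 45,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  flt <- apply_filters(freqs, met_cohort, primary_cohort,
                       frequent_cutoff, infrequent_cutoff)
  tab <- flt$table
  met <- freqs[freqs$cohort == met_cohort, ]
  prim <- freqs[freqs$cohort == primary_cohort, ]
  tab$p_value <- vapply(tab$gene, function(g) {
    mrow <- met[met$gene == g, ][1, ]
    prow <- prim[prim$gene == g, ][1, ]
    if (anyNA(c(mrow$n_evaluable, prow$n_evaluable))) return(NA_real_)
    differential_test(mrow$n_methylated, mrow$n_evaluable,
                      prow$n_methylated, prow$n_evaluable)
  }, numeric(1))
  if (adjust == "BH") tab$p_adjusted <- stats::p.adjust(tab$p_value, "BH")
  tab[, c("gene", "freq_met", "freq_primary", "p_value",
          if (adjust == "BH") "p_adjusted", "frequent_in_met", "selected")]
}
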