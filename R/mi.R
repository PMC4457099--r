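#' Clone bisulfite-sequencing matrices
#'
#' Rows are sequenced clones (individual alleles), columns are CpG
#' positions of one amplicon in one sample. States are `1` (methylated),
#' `0` (unmethylated) or `NA` (missing / not readable).
#'
#' @param states numeric/logical matrix of 0/1/NA, clones x CpG sites.
#' @param gene gene symbol of the amplicon.
#' @param sample sample identifier.
#' @return A `clone_matrix` object.
#' @export
clone_matrix <- function(states, gene = "gene", sample = "sample") {
  stopifnot(is.matrix(states), nrow(states) >= 1, ncol(states) >= 1)
  storage.mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L, NA_integer_)))
    stopf("clone states must be 0, 1 or NA")
  if (all(is.na(states)))
    stopf("clone matrix for %s/%s has no informative state", gene, sample)
  structure(states, gene = gene, sample = sample,
            class = c("clone_matrix", class(states)))
}

#' Methylation index of a clone matrix
#'
#' The methylation index (MI) is the number of methylated CpG
#' dinucleotides as a percentage of all CpGs analysed, pooled over every
#' clone and CpG column (a micro-average, not a per-clone mean). The
#' classification bands follow the calibration of CoBRA against
#' clone sequencing: MI >= 60 is methylated, MI < 40 unmethylated, and the
#' never-observed 40-60 zone is reported as ambiguous.
#'
#' @param cm a [clone_matrix].
#' @return An `mi_result` list: `mi` (percentage), `n_informative`,
#'   `classification`.
#' @export
compute_mi <- function(cm) {
  stopifnot(inherits(cm, "clone_matrix"))
  obs <- cm[!is.na(cm)]
  if (length(obs) == 0) stopf("all clone states missing")
  mi <- 100 * sum(obs == 1L) / length(obs)
  structure(list(mi = mi,
                 n_informative = length(obs),
                 classification = classify_mi(mi)),
            class = "mi_result")
}

#' Classify a methylation-index percentage
#' @param mi percentage in `[0, 100]`.
#' @param methylated_min lower inclusive bound of the methylated band
#'   (default 60).
#' @param unmethylated_max exclusive upper bound of the unmethylated band
#'   (default 40).
#' @return `"methylated"`, `"unmethylated"` or `"ambiguous"`.
#' @export
classify_mi <- function(mi, methylated_min = 60, unmethylated_max = 40) {
  stopifnot(mi >= 0, mi <= 100, unmethylated_max <= methylated_min)
  if (mi >= methylated_min) "methylated"
  else if (mi < unmethylated_max) "unmethylated"
  else "ambiguous"
}

#' Concordance between clone-sequencing MI and CoBRA calls
#'
#' Fraction of samples where the CoBRA call and the MI classification agree
#' on "methylated"; an ambiguous MI is discordant with either CoBRA call.
#'
#' @param mi_results list of `mi_result` objects (or character
#'   classifications).
#' @param cobra_calls character vector of CoBRA calls (`"methylated"` /
#'   `"unmethylated"`), parallel to `mi_results`.
#' @return fraction in `[0, 1]`.
#' @export
mi_concordance <- function(mi_results, cobra_calls) {
  if (length(mi_results) == 0) stopf("no MI/CoBRA pairs to compare")
  if (length(mi_results) != length(cobra_calls))
    stopf("mi_results and cobra_calls must have equal length")
  cls <- vapply(mi_results, function(r)
    if (inherits(r, "mi_result")) r$classification else as.character(r),
    character(1))
  check_calls(cobra_calls[cobra_calls != "failed"], "CoBRA")
  agree <- (cls == "methylated" & cobra_calls == "methylated") |
           (cls == "unmethylated" & cobra_calls == "unmethylated")
  mean(agree)
}

#' Read a clone-state CSV
#'
#' Rows are clones, columns CpG positions; cells are `M` (methylated),
#' `U` (unmethylated) or `.` (missing). The gene and sample are taken from
#' the filename `gene_sample.csv` unless given.
#'
#' @param path CSV path.
#' @param gene,sample identifiers; defaults parsed from the filename.
#' @return A [clone_matrix].
#' @export
read_clone_matrix <- function(path, gene = NULL, sample = NULL) {
  base <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (is.null(gene)) gene <- parts[1]
  if (is.null(sample)) sample <- if (length(parts) > 1)
    paste(parts[-1], collapse = "_") else "sample"
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  m <- as.matrix(df)
  bad <- setdiff(unique(as.vector(m)), c("M", "U", "."))
  if (length(bad) > 0)
    stopf("invalid clone state(s) in %s: %s", path, paste(bad, collapse = ", "))
  states <- matrix(NA_integer_, nrow(m), ncol(m))
  states[m == "M"] <- 1L
  states[m == "U"] <- 0L
  clone_matrix(states, gene = gene, sample = sample)
}

#' Write a clone-state CSV
#' @param cm a [clone_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clone_matrix <- function(cm, path) {
  m <- matrix(".", nrow(cm), ncol(cm))
  m[which(cm == 1L)] <- "M"
  m[which(cm == 0L)] <- "U"
  colnames(m) <- paste0("cpg", seq_len(ncol(cm)))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
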