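#' Beta-value matrices
#'
#' A beta matrix holds per-probe, per-sample methylation fractions
#' (array-style beta values) for one cohort. Values lie in `[0, 1]`;
#' missing values are `NA`.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param cohort single string labelling the cohort.
#' @return A `beta_matrix` object (the matrix with attributes).
#' @export
beta_matrix <- function(values, cohort) {
  stopifnot(is.matrix(values), is.character(cohort), length(cohort) == 1)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate probe ids in beta matrix")
  storage.mode(values) <- "double"
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("beta value out of [0,1] at probe %s, sample %s",
          rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  structure(values, cohort = cohort,
            class = c("beta_matrix", class(values)))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> cohort '%s': %d probes x %d samples\n",
              attr(x, "cohort"), nrow(x), ncol(x)))
  invisible(x)
}

cohort_label <- function(bm) attr(bm, "cohort")

#' Read a beta-value TSV
#'
#' Tab-separated, first column `probe_id`, one column per sample. Empty
#' fields and `NA` are treated as missing; values outside `[0, 1]` are a
#' hard error naming the offending cell.
#'
#' @param path path to the TSV file.
#' @param cohort cohort label to attach.
#' @return A [beta_matrix].
#' @export
read_beta_matrix <- function(path, cohort) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "probe_id")
    stopf("beta TSV %s must have 'probe_id' first column plus >=1 sample", path)
  probes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad_parse <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad_parse) > 0)
    stopf("unparseable beta value '%s' at probe %s, sample %s in %s",
          vals[bad_parse[1, , drop = FALSE]],
          probes[bad_parse[1, 1]], colnames(vals)[bad_parse[1, 2]], path)
  rownames(num) <- probes
  colnames(num) <- colnames(vals)
  beta_matrix(num, cohort)
}

#' Write a beta-value TSV
#' @param bm a [beta_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path) {
  df <- data.frame(probe_id = rownames(bm), as.data.frame(unclass(bm)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
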