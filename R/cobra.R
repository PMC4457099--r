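#' Methylated amplicon sequences
#'
#' A `methylated_sequence` couples one amplicon (top strand, A/C/G/T) with
#' the positions of its CpG cytosines and a parallel vector of methylation
#' states. Positions are 1-based within R; file interchange uses 0-based
#' coordinates (see [read_methylation_states]).
#'
#' @param seq single nucleotide string over A/C/G/T.
#' @param cpg_positions integer vector, 1-based index of the C of each CpG.
#' @param methyl_states character vector parallel to `cpg_positions`, each
#'   `"methylated"` or `"unmethylated"`.
#' @return A `methylated_sequence` object.
#' @export
methylated_sequence <- function(seq, cpg_positions, methyl_states) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stopf("sequence contains characters outside A/C/G/T")
  cpg_positions <- as.integer(cpg_positions)
  if (length(cpg_positions) != length(methyl_states))
    stopf("cpg_positions and methyl_states must be parallel")
  if (anyDuplicated(cpg_positions))
    stopf("duplicate CpG positions")
  bad_state <- setdiff(unique(methyl_states), c("methylated", "unmethylated"))
  if (length(bad_state) > 0)
    stopf("invalid methylation state(s): %s", paste(bad_state, collapse = ", "))
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in cpg_positions) {
    if (p < 1 || p >= n || chars[p] != "C" || chars[p + 1] != "G")
      stopf("position %d is not the C of a CpG dinucleotide", p)
  }
  structure(list(seq = seq,
                 cpg_positions = cpg_positions,
                 methyl_states = as.character(methyl_states)),
            class = "methylated_sequence")
}

#' Locate all CpG dinucleotides in a sequence
#' @param seq nucleotide string.
#' @return 1-based integer positions of each CpG cytosine.
#' @export
find_cpg_sites <- function(seq) {
  hits <- gregexpr("(?=CG)", toupper(seq), perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' In-silico bisulfite conversion
#'
#' Deaminates every cytosine that is not a methylated CpG cytosine to
#' thymine (uracil, read as T after PCR); methylated CpG cytosines are
#' protected. Conversion is complete by default; `error_rate > 0` leaves
#' each convertible cytosine unconverted with that probability (incomplete
#' conversion, drawn from the current RNG stream).
#'
#' @param ms a [methylated_sequence].
#' @param error_rate probability that a convertible C escapes conversion
#'   (default 0).
#' @return converted nucleotide string.
#' @export
bisulfite_convert <- function(ms, error_rate = 0) {
  stopifnot(inherits(ms, "methylated_sequence"),
            error_rate >= 0, error_rate <= 1)
  chars <- strsplit(ms$seq, "")[[1]]
  protected <- ms$cpg_positions[ms$methyl_states == "methylated"]
  convert <- which(chars == "C")
  convert <- setdiff(convert, protected)
  if (error_rate > 0 && length(convert) > 0)
    convert <- convert[stats::runif(length(convert)) >= error_rate]
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

# Restriction enzymes used by CoBRA. Both recognition sites retain their CpG
# only when the CpG was methylated, so digestion reports methylation.
# cut_offset: cut occurs after this many bases of the site (top strand).
COBRA_ENZYMES <- list(
  BstUI = list(site = "CGCG", cut_offset = 2L),  # CG^CG, blunt
  TaqI  = list(site = "TCGA", cut_offset = 1L)   # T^CGA
)

#' In-silico restriction digestion of a converted amplicon
#'
#' Scans the top strand for all (possibly overlapping) occurrences of the
#' enzyme's recognition site and cuts at the enzyme's offset within each
#' site. Both CoBRA enzymes (BstUI `CGCG`, TaqI `TCGA`) have palindromic
#' sites, so the top strand determines site presence on double-stranded PCR
#' product.
#'
#' @param converted nucleotide string (typically from [bisulfite_convert]).
#' @param enzyme `"BstUI"` or `"TaqI"`.
#' @return A `digest_result` list: `enzyme`, `cut_positions` (1-based,
#'   cut after this base), `fragment_lengths`, `call` (`"methylated"` iff
#'   at least one cut).
#' @export
digest_sequence <- function(converted, enzyme = names(COBRA_ENZYMES)) {
  enzyme <- match.arg(enzyme)
  stopifnot(is.character(converted), length(converted) == 1)
  converted <- toupper(converted)
  if (nchar(converted) == 0) stopf("cannot digest an empty sequence")
  if (grepl("[^ACGT]", converted))
    stopf("sequence contains characters outside A/C/G/T")
  def <- COBRA_ENZYMES[[enzyme]]
  starts <- gregexpr(paste0("(?=", def$site, ")"), converted, perl = TRUE)[[1]]
  starts <- if (starts[1] == -1) integer(0) else as.integer(starts)
  cuts <- sort(unique(starts - 1L + def$cut_offset))
  n <- nchar(converted)
  fragment_lengths <- diff(c(0L, cuts, n))
  fragment_lengths <- fragment_lengths[fragment_lengths > 0]
  structure(list(enzyme = enzyme,
                 cut_positions = cuts,
                 fragment_lengths = as.integer(fragment_lengths),
                 call = if (length(cuts) > 0) "methylated" else "unmethylated"),
            class = "digest_result")
}

#' Full CoBRA assay on one allele
#'
#' Bisulfite-converts the amplicon once, digests the converted product with
#' each requested enzyme, and calls the allele methylated if any enzyme
#' cuts.
#'
#' @param ms a [methylated_sequence].
#' @param enzymes character vector of enzymes (default both).
#' @param error_rate incomplete-conversion rate passed to
#'   [bisulfite_convert].
#' @return A `cobra_result` list: `converted`, `digests` (one
#'   `digest_result` per enzyme), `call`.
#' @export
cobra_assay <- function(ms, enzymes = names(COBRA_ENZYMES), error_rate = 0) {
  enzymes <- match.arg(enzymes, several.ok = TRUE)
  converted <- bisulfite_convert(ms, error_rate = error_rate)
  digests <- lapply(enzymes, function(e) digest_sequence(converted, e))
  names(digests) <- enzymes
  call <- if (any(vapply(digests, `[[`, character(1), "call") == "methylated"))
    "methylated" else "unmethylated"
  structure(list(converted = converted, digests = digests, call = call),
            class = "cobra_result")
}

#' Semi-quantitative CoBRA call over a pool of alleles
#'
#' A tumour sample is a pool of alleles; the gel shows digestion products
#' when a sufficient fraction of the pool is cut. The pool is called
#' methylated when the fraction of alleles with at least one cut exceeds
#' `cut_fraction` (strictly greater, so a pool at exactly the threshold is
#' not called).
#'
#' @param alleles list of [methylated_sequence] objects sharing one
#'   amplicon.
#' @param enzymes enzymes to apply.
#' @param cut_fraction minimum allele fraction cut for a methylated call
#'   (default 0.25).
#' @param error_rate incomplete-conversion rate per allele.
#' @return list: `call`, `cut_fraction_observed`, `n_alleles`.
#' @export
cobra_pool <- function(alleles, enzymes = names(COBRA_ENZYMES),
                       cut_fraction = 0.25, error_rate = 0) {
  stopifnot(length(alleles) > 0)
  cut <- vapply(alleles, function(a)
    cobra_assay(a, enzymes, error_rate)$call == "methylated", logical(1))
  frac <- mean(cut)
  list(call = if (frac > cut_fraction) "methylated" else "unmethylated",
       cut_fraction_observed = frac,
       n_alleles = length(alleles))
}
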