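# Independent oracles. These deliberately use naive enumeration / nested
# loops so they share no code path with the implementation they check.

# Two-sided Fisher exact p by direct hypergeometric enumeration (lchoose).
oracle_fisher <- function(a, n1, c_, n2) {
  m <- a + c_
  xs <- max(0, m - n2):min(m, n1)
  lp <- lchoose(n1, xs) + lchoose(n2, m - xs) - lchoose(n1 + n2, m)
  p <- exp(lp)
  p_obs <- p[xs == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Nested-loop prevalence screen over a plain matrix.
oracle_screen <- function(values, mode, config = screen_config()) {
  pass <- character(0)
  for (i in seq_len(nrow(values))) {
    row <- values[i, ]
    n_obs <- 0L; hits <- 0L
    for (v in row) {
      if (is.na(v)) next
      n_obs <- n_obs + 1L
      if (mode == "unmethylated" && v <= config$unmeth_beta_max)
        hits <- hits + 1L
      if (mode == "methylated" && v >= config$meth_beta_min)
        hits <- hits + 1L
    }
    if (n_obs < config$min_informative_frac * ncol(values) || n_obs == 0)
      next
    frac_needed <- if (mode == "unmethylated") config$unmeth_sample_frac
                   else config$meth_sample_frac
    if (hits / n_obs >= frac_needed) pass <- c(pass, rownames(values)[i])
  }
  pass
}

# All start positions of `site` in `seq` by character-wise scan.
oracle_sites <- function(seq, site) {
  n <- nchar(seq); k <- nchar(site)
  out <- integer(0)
  for (i in seq_len(max(0, n - k + 1)))
    if (substr(seq, i, i + k - 1) == site) out <- c(out, i)
  out
}

# Position-by-position bisulfite conversion.
oracle_convert <- function(seq, cpg_positions, states) {
  chars <- strsplit(seq, "")[[1]]
  meth <- cpg_positions[states == "methylated"]
  for (i in seq_along(chars))
    if (chars[i] == "C" && !(i %in% meth)) chars[i] <- "T"
  paste(chars, collapse = "")
}

random_beta_values <- function(nr, nc, na_frac = 0.05) {
  v <- matrix(runif(nr * nc), nr, nc,
              dimnames = list(sprintf("p%03d", seq_len(nr)),
                              sprintf("s%03d", seq_len(nc))))
  v[runif(nr * nc) < na_frac] <- NA
  v
}

random_methylated_sequence <- function(len = 80) {
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
  cpg <- find_cpg_sites(seq)
  states <- sample(c("methylated", "unmethylated"), length(cpg),
                   replace = TRUE)
  methylated_sequence(seq, cpg, states)
}
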