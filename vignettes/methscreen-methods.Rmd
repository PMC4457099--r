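---
title: "Methods: promoter hypermethylation screening for metastatic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter hypermethylation screening for metastatic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscreen)
```

# The model and its assumptions

`methscreen` implements a candidate-gene screen for promoter CpG-island
hypermethylation in tumours that metastasise, in the form used for
breast-to-brain metastasis (BBM). The underlying biological model is that
promoter island methylation silences a gene, and that genes silenced in the
metastasis but not in unrelated primary tumours are candidate metastasis
suppressors. Three measurement layers are modelled:

* **Array beta values.** A probe's beta value is the methylated fraction of
  signal at one CpG, in [0, 1]. We treat a sample as unmethylated at a
  probe when β ≤ 0.25 and methylated when β ≥ 0.60; values between are
  considered uninformative for the screen. A probe is *infrequently
  methylated* in a cohort when the unmethylated state holds in at least
  75 % of samples, *frequently methylated* when the methylated state holds
  in at least 50 %. All four comparisons are inclusive, matching the
  "at least 15/20" phrasing of the design.
* **CoBRA.** Bisulfite treatment converts unmethylated cytosine to uracil
  (read as thymine after PCR) while 5-methylcytosine is protected. The
  BstUI (`CGCG`) and TaqI (`TCGA`) recognition sites each contain a CpG,
  so a site survives (or is created) in the converted amplicon only when
  its CpG was methylated; digestion therefore reports methylation. We model
  complete conversion by default, digestion on the top strand only (both
  sites are palindromic, so strand choice cannot change site presence), and
  binarize the gel readout as ≥ 1 cut ⇒ methylated. For allele pools,
  `cobra_pool()` exposes the minimal cut fraction as a parameter (default:
  fraction > 0.25 ⇒ methylated) because the original readout — "clearly
  observed digest products" — is qualitative and the required fraction was
  never stated.
* **Clone sequencing.** The methylation index (MI) of an amplicon in a
  sample is the percentage of methylated CpGs among all CpGs analysed,
  pooled over clones × positions (a micro-average; this is what "total
  number of methylated CpG dinucleotides as a percentage of all CpGs
  analysed" computes, and it weights clones by their informative CpGs).

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `unmeth_beta_max` | 0.25 | beta | published unmethylated threshold |
| `unmeth_sample_frac` | 0.75 | fraction | published 15/20 prevalence |
| `meth_beta_min` | 0.60 | beta | published methylated threshold |
| `meth_sample_frac` | 0.50 | fraction | published 10/20 prevalence |
| `accepted_tss_groups` | TSS200, TSS1500 | — | promoter definition (≤ 1500 bp of TSS) |
| `min_informative_frac` | 0.5 | fraction | probes with < 50 % non-missing betas are unevaluable |
| `frequent_cutoff` | 50 | % | frequent-in-metastasis gene filter |
| `infrequent_cutoff` | 45 | % | infrequent-in-primary gene filter |
| MI bands | ≥ 60 / < 40 | % | CoBRA-calibrated methylated / unmethylated bands |
| `cut_fraction` | 0.25 | fraction | allele pool fraction for a CoBRA call |
| `early_frac`, `late_frac` | 0.5 | fraction | matched-pair timing rule |

Design notes on the less obvious rows:

* The promoter vocabulary of 450K-style manifests has no standalone "TSS"
  category; the design's "TSS, TSS200, TSS1500" is read as membership in
  TSS200 or TSS1500, configurable via `accepted_tss_groups`.
* Missing beta values are excluded from both the numerator and denominator
  of prevalence; a probe with under half its samples informative is flagged
  unevaluable rather than screened on a sliver of data. The source design
  is silent here; this choice avoids prevalence estimates from tiny
  denominators.
* Probes annotating several genes fan out to all of them (manifest
  semantics); gene-level island gating asks whether *any* supporting probe
  is island-annotated, keeping the screen self-contained on the annotation
  table instead of requiring an external island track.
* The MI band between 40 and 60 % was never named in the original
  calibration (observed MIs were 0–36 % and 60–91 %); we classify it
  `ambiguous` and treat it as discordant in `mi_concordance()` rather than
  inventing a call.
* The timing rule quantifies a qualitative judgement: among evaluable pairs
  whose metastasis is methylated, the fraction `f` with a methylated
  primary decides `early` (`f ≥ 0.5`) versus `late` (`f ≤ 0.5`); exactly
  0.5 resolves to `early` (the tie must go somewhere; `early` is the
  conservative claim that methylation was already detectable in the
  primary), and with stricter non-default thresholds an intermediate zone
  is labelled `mixed`. Adjacent-normal calls are carried through but never
  used by the rule, since the original design showed a normal lane only
  illustratively.
* The Fisher test is two-sided and exact (summing hypergeometric
  probabilities ≤ that of the observed table, with a 1e-7 relative guard
  for floating-point ties). The original analysis never names its test;
  Fisher's exact is the standard choice for 2×2 tables at these counts, so
  reproduced p-values are expected to match the printed ones in order of
  magnitude, not digit-for-digit. No multiple-testing correction is applied
  by default (none was applied originally); `adjust = "BH"` is available.

# What the synthetic generator emulates

`sim_config()` states the simulated world once, at the scale of the
original study: 20 samples per discovery cohort (array stage), 30
metastases and 40 independent primaries (validation stage), 10 matched
pairs per gene, 10 clones × 20 CpGs per amplicon, and a 2 % call-flip
noise that jointly stands in for assay failure and biological
heterogeneity. Betas are drawn from a two-component mixture — Beta(2,8)
unmethylated, Beta(8,2) methylated — chosen to straddle the 0.25/0.60
thresholds with realistic overlap. Background (non-planted) probes may
also be `intermediate`, drawing from Beta(5,5): this represents
hemimethylation-like intermediate methylation as intermediate beta
*levels*. An earlier design that represented intermediate probes as a
50/50 bimodal mixture of samples was discarded as ill-posed: such probes
sit exactly on the ≥ 50 % prevalence decision boundary, so no screen could
classify them consistently and "truth" was undefined.

The planted structure is: 8 differential probes (unmethylated-in-breast,
methylated-in-lung, promoter, island) among 500 background probes whose
state pairs never mimic that combination; and a 20-gene validation panel
with 2 planted `late` genes, 1 planted `early` gene and 17 background
`none` genes. `early` genes are methylated in the metastasis *and* in the
matched primaries of metastasising patients, but not in the independent
(non-metastasising) primary cohort — exactly the pattern that makes an
early epimutation pass the ≤ 45 % filter on unrelated primaries while
showing concordant matched pairs.

What a green test does **not** establish: the generator has no probe-type
chemistry (type I/II), no batch effects, no copy-number confounding, no
spatial correlation along the island, and clone states are i.i.d. across
CpGs (real alleles are strongly autocorrelated). Exact screen-stage
probe recovery is only guaranteed under `complete_separation = TRUE`
(betas from U[0, 0.15] / U[0.8, 1] / U[0.3, 0.55]); at the default
overlapping mixtures, occasional background probes legitimately pass both
prevalence screens, which is why end-to-end recovery is scored on the
selected genes and timing labels.

# Numerical choices and degenerate inputs

* All threshold comparisons are inclusive; frequencies are filtered
  unrounded and only formatted to one decimal for reporting.
* Overlapping restriction sites are all counted (`CGCGCG` has two BstUI
  sites); cut positions are deduplicated before fragment computation, and
  fragment lengths always sum to the amplicon length.
* Degenerate inputs fail loudly: an all-missing beta row, an all-missing
  clone matrix, a gene with zero evaluable pairs, and a zero-total Fisher
  table are errors; a gene missing one cohort is excluded with a warning;
  a gene with zero evaluable samples in a cohort is reported flagged with
  an undefined frequency rather than a fabricated zero.
* Interchange coordinates (CpG positions in state sidecar files) are
  0-based on disk, 1-based inside R, converted at the I/O boundary only.
* RNG: every generator derives its stream from `sim_config(seed)` via a
  per-stage offset, so stages are reproducible independently and jointly.

# Known limitations

* The screen consumes finished beta values; no normalization, probe QC or
  IDAT handling.
* CoBRA modelling ignores PCR bias, primer design and partial digestion;
  incomplete bisulfite conversion is available only as a simulation
  error-rate parameter (default 0).
* The timing classifier cannot distinguish a truly late epimutation from
  methylation present in a primary subclone below assay detection; this
  caveat is inherent to the assay, not recoverable from these data.
* Printed frequency tables without denominators (`bbm_frequency_table()`)
  support filtering but not exact tests; `n_evaluable` is therefore always
  reported and `NA` where unknown.
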