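Package: methscreen
Title: Promoter Hypermethylation Candidate Screening for Metastatic Tumour Cohorts
Version: 0.1.0
Authors@R: person("Brain Tumour Methylation", "Screen Maintainers", role = c("aut", "cre"),
    email = "maintainer@methscreen.invalid")
Description: A tested pipeline for identifying candidate metastasis-associated
    genes silenced by promoter CpG-island hypermethylation. Implements
    450K-style beta-value prevalence screening across tumour cohorts,
    in-silico combined bisulfite restriction analysis (CoBRA) with BstUI and
    TaqI digestion, clone bisulfite-sequencing methylation-index computation,
    cohort frequency filtering with Fisher exact differential tests, and
    matched primary/metastasis pair classification of epimutation timing.
    Includes a synthetic-data module that generates every input format with
    recorded ground truth, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
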