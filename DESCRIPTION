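Package: mtassoc
Title: Case-Control Association Analysis of Whole Mitochondrial Genome Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates mitochondrial single-nucleotide variants against an
    rCRS-coordinate gene model, assigns mtDNA haplogroups by concordance with a
    phylotree-style marker tree, classifies variants (transition/transversion,
    synonymous/non-synonymous, rare/common by population frequency), computes
    regional burden tables and pathogenicity-score variant loads, and runs the
    case-control association statistics used in whole-mtDNA studies: two-sided
    Fisher exact tests, Haldane-Anscombe-corrected odds ratios, Woolf logit
    confidence intervals and pooled-variance t-tests. Includes a synthetic
    cohort generator so the whole pipeline is testable without sequence
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
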