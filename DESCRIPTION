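Package: rnadriver
Title: Cancer Driver Gene Detection from RNA Variant Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative cancer driver genes in paired DNA/RNA-seq
    tumor cohorts from the RNA variant allele frequencies (RNA VAFs) of
    somatic single-nucleotide variants. Nonsynonymous mutations in each gene
    are compared against a hierarchically sampled synonymous background with
    a weighted one-sided linear model, bootstrapped 25 times and aggregated
    by the geometric mean p value, with Benjamini-Hochberg correction and a
    q < 0.25 driver call. Includes nonsense-mediated decay (NMD) scaling of
    nonsense-mutation VAFs, cancer cell fraction and mutant copy-number
    estimation, a copy-number-aware beta-binomial allele-specific expression
    test, benchmarking utilities (CGC score, Fisher enrichment, expression
    odds ratios, VAF-based AUC), and a synthetic-cohort simulator with known
    ground truth for calibration experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
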