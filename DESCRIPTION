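Package: gbskit
Title: Quality Control, Simulation and Imputation Evaluation for
    Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating reduced-representation
    genotyping-by-sequencing (GBS) assays in outbred diploid populations.
    Provides in-silico single and double restriction digestion with
    fragment-size summaries, coverage-based empirical fragment counting, a
    synthetic GBS genotype simulator with negative-binomial read depths,
    likelihood-based genotype calling and phred-scaled genotype qualities, a
    two-step variant quality-control cascade (per-call read-depth/GQ
    filtering followed by call-rate/MAF/biallelic variant filtering),
    concordance-based genotype accuracy against a designated truth panel,
    and masking-based evaluation of genotype imputation with dense-panel
    merging. Closed-form calculators for heterozygote miscall probability
    at low read depth and phred conversions are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
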