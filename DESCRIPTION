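Package: transig
Title: Translational Sequence Signatures of Stably Expressed Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links codon-level translational signatures of human protein-coding
    genes (tRNA adaptation index, codon adaptation index, coding and UTR
    lengths, 5'-end mRNA folding energy, amino-acid usage) to steady-state
    mRNA levels in cohorts of stably expressed genes. Provides sequence
    quality control and longest-isoform collapsing, codon and amino-acid
    feature computation, a self-contained minimum-free-energy folder for
    fixed 50-nt windows, expression-based gene-group assembly, Spearman
    correlation tables, penalized stepwise linear-model selection with LMG
    relative-importance decomposition and bootstrap confidence intervals,
    nonparametric group comparisons, pooled gene-category frequency tests,
    and a calibrated synthetic-data generator that emulates the statistical
    structure of stably expressed gene sets so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
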