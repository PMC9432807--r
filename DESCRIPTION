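Package: scSomaticAging
Title: Ploidy-Aware Somatic SNV Burden and Aging Analysis for Single-Cell WGS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating somatic single-nucleotide variant (sSNV)
    burden from whole-genome-amplified single cells and relating it to donor
    age. Implements a phasing/linkage-based somatic caller with per-cell
    precision-calibrated read thresholds, amplification quality control
    (locus/allelic dropout, MAPD, CoV), a dropout decomposition that corrects
    detection sensitivity in tetraploid nuclei, 96-context mutational
    signature discovery by NMF with cophenetic rank selection and artifact
    subtraction, linear mixed-effects aging models, mutation spectrum and
    transcriptional strand-bias analysis, gene-length-aware functional
    enrichment, and a ploidy-aware gene-knockout probability model. A fully
    specified synthetic single-cell WGS cohort generator (phased germline
    hets, age-linear somatic truth, MDA dropout/unevenness/artifact models,
    in-silico tetraploid mixtures) makes the whole pipeline testable without
    access to controlled human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    lme4,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
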