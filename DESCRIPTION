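Package: cardiodiv
Title: Cardiac Progenitor Cell-Division Phenotype Analysis for the Drosophila Embryonic Heart
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and testing cardiac progenitor cell-division
    defects in the Drosophila embryonic heart. Simulates embryo cohorts under a
    stereotyped heart-lineage model with parameterized division-error rates,
    classifies per-hemisegment cell counts into symmetric, asymmetric, and
    earlier-stage division defect categories (with and without pericardial-cell
    information), summarizes defect proportions per embryo, and tests genotype
    effects and gene-gene synergy with permutation tests of regression
    coefficients, including a Smith-orthogonalization permutation test of the
    interaction term. Also provides differential-expression threshold gating,
    2^-ddCt relative-quantification with one-tailed Welch tests, and a
    ChIP-peak clustering triage of likely direct transcription-factor targets
    over intronic and intergenic gene territories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
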