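Package: cfduplex
Title: Duplex UMI Consensus Calling, Error Profiling and Matched-Normal
    Filtering for Cell-Free DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a duplex unique-molecular-identifier (UMI)
    deep-sequencing workflow for circulating cell-free DNA: collapsing of
    UMI-tagged read pairs into duplex/simplex/sub-simplex/singleton consensus
    tiers with end trimming, per-position substitution error profiling across
    tiers, threshold-based low-VAF variant detection (de novo and genotyping
    modes), matched white-blood-cell filtering of germline and clonal
    hematopoiesis variants with population-database support, an allele-specific
    cfDNA fragment-length bootstrap test, and exact binomial (Clopper-Pearson)
    assay validation statistics. Includes a synthetic read simulator emulating
    bimodal cfDNA fragment lengths, PCR strand families and injected somatic,
    germline and clonal hematopoiesis variants, so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
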