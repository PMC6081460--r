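Package: oncomark
Title: Comparative Chromatin-Mark Analysis for Oncohistone Mutants
Version: 1.0.0
Authors@R:
    person("Oncomark", "Maintainers", email = "maintainers@oncomark.dev",
           role = c("aut", "cre"))
Description: Bin-level ChIP-seq quantitation and normalization (per-million and
    distribution matching), percentile-based calling of mark-enriched genic
    regions with merge/length/extreme-value filtering, stratification of
    regions by factor occupancy, fold-change classification against a knockout
    reference cohort, RPKM expression comparison over gene sets with random
    controls, allele-informative RNA-seq read classification at histone H3
    codon 34, and MALDI methylation-state quantitation from peptide spectra.
    Includes seeded synthetic-data generators with planted ground truth so the
    whole pipeline runs and is verified at desk scale, plus a command-line
    front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Rsamtools
Config/testthat/edition: 3
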