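Package: canrec
Title: Pedigree-Based Recombination Maps and Crossover Interference in the Dog Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pedigree-based analysis of meiotic recombination in the
    domestic dog. Builds sex-specific genetic maps from crossover calls using an
    effective-meioses correction and Haldane's map function, applies robust
    quality-control filters (call probability, blacklist regions, clustered
    double-crossover removal, MAD-based outlier meioses), computes broad- and
    fine-scale landscape statistics (telomeric proportions, recombination
    concentration curves with chromosome bootstrap, TSS/CpG-island rate
    profiles, marker-framework thinning for cross-map comparisons), and fits
    crossover-interference models (stationary thinned gamma renewal and the
    Housworth-Stahl gamma-escape mixture) by maximum likelihood with bootstrap
    confidence intervals and BIC model selection. Includes a synthetic meiosis
    simulator so every stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
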