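Package: panbac
Title: Bacterial Pan-Genome Analysis, Rarefaction Curve Fitting and
    Niche-Associated Gene Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of bacterial pan-genomes:
    ortholog family construction from proteomes by bidirectional best
    hits at a 50% identity / 50% coverage regime, core/dispensable/
    strain-unique partitioning, pan- and core-genome rarefaction with
    power-law and exponential-decay curve fitting (Heaps-law openness),
    MinHash genome sketching with Mash distances, ANI-based species
    delineation at the 95% threshold, detection of niche-associated
    accessory gene families, and COG functional-category enrichment by
    Fisher's exact test.  A synthetic pan-genome simulator with known
    gene gain/loss history, planted niche-specific families and COG
    labels supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    methods,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
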