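Package: hsgwas
Title: Genotype-by-In-Utero Heat Stress Interaction GWAS
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for time-lagged (in-utero) heat-stress interaction
    genome-wide association studies in dairy cattle. Builds weekly
    temperature-humidity-index (THI) exposures from hourly weather records,
    applies marker and animal quality control, constructs VanRaden genomic
    relationship matrices, estimates variance components with a
    genotype-by-heat-stress interaction term by AI-REML, runs a per-SNP
    generalized-least-squares scan for main and interaction effects with
    inflation diagnostics and LD-pruning-based significance thresholds, and
    annotates hits against candidate-gene windows. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
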