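Package: matefit
Title: Pooled Competition Fitness Analysis for Peptide Pheromone Variant Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deep-mutational-scanning-style pooled competition assays
    of the fission yeast mating pheromone M-factor. Enumerates a barcoded
    single-substitution variant library, forward-simulates repeated
    mating-germination selection cycles under condition-dependent mating
    efficiency and emits amplicon FASTQ reads, demultiplexes reads into
    genotype counts via a motif-anchored 24-bp barcode, computes log2
    fold-change enrichment statistics with replicate-level Welch tests and
    volcano classification, predicts pooled outcomes from single-strain mating
    efficiencies, and evaluates single-strain assay formulas (microscopy
    mating rate, Miller units, growth lag) and double-mutant buffering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    stringi,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
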