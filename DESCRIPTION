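Package: ystrata
Title: Dating Sex-Chromosome Recombination Suppression and Testing
    Origin Models in Poeciliid Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven inference pipeline for the evolutionary
    history of poeciliid XY sex chromosomes. Provides pedigree-based
    segregation typing (autosomal/XY/X0) with X-Y phasing, an expression
    screen for highly diverged Y genes, male:female read-depth
    classification of contigs and pseudoautosomal-region boundary
    detection, NG86 synonymous-divergence (dS) dating of gametologs,
    neighbor-joining gene trees with bootstrap support and topology
    classification, canonical k-mer analysis of male-specific sequence
    (Y-mers) with a female-specific false-positive control, and a
    synthetic-data generator that plants ground truth under three
    competing models of sex-chromosome origin (Parsimony, Turnover,
    Homology) so that every stage of the pipeline is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
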