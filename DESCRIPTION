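Package: phageHoming
Title: Interference Competition by Intron Homing Endonucleases in
    Co-Infecting Bacteriophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and quantifies interference competition between
    co-infecting nucleus-forming bacteriophages mediated by an
    intron-encoded homing endonuclease. Provides a stochastic per-cell
    co-infection simulator with a closed-form expectation for the
    competitor fold-change, inference of interference strength from
    observed fold-changes, multi-generation homing/interference
    dynamics, plaque-assay summary statistics (efficiency of plating,
    fold-change, ratio-paired and unpaired t-tests), sequence-level
    genetics of the intron insertion site (insertion-point detection,
    homologous target mapping, escaper classification, silent
    recoding), synthetic fluorescence-image quantification of
    intracellular DNA distribution, and synthetic-data generators for
    every input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    EBImage,
    pracma,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, Alignment, CellBasedAssays
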