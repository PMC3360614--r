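Package: mirest
Title: Homology-Based MicroRNA Discovery and Annotation from EST Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering microRNA candidates in un-annotated
    expressed sequence tag (EST) collections by homology to known mature
    miRNAs, validating candidate precursors by stem-loop thermodynamics under
    a packaged nearest-neighbor energy model, grouping mature miRNAs into
    families by nomenclature, quantifying relative expression from stem-loop
    RT-PCR band intensities (log10 ratio to a U6 snRNA control), and
    predicting seed-match and 3'-fragment hybridization target sites in 3'UTR
    sets under a duplex free-energy filter. Includes a synthetic-data
    generator with planted ground truth for recovery benchmarking, an exact
    exhaustive-enumeration oracle for the folding dynamic program, and
    packaged catalogue fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    tibble,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
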