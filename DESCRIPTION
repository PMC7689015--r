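Package: intrasv
Title: Intraspecific Genome Comparison: Structural Variants, Repeat
    Landscapes, Copy Number and Genome Size
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of two intraspecific genome assemblies:
    unique-anchor alignment into collinear blocks, detection of
    genome-specific regions and inversions from filtered block tables,
    Table-style region summaries, per-chromosome repeat landscapes with
    chi-square homogeneity tests, read-depth copy-number estimation of
    repeat families calibrated on single-copy genes, neighbor-joining
    phylogenies of repeat sequences under the Jukes-Cantor model, and
    flow-cytometry genome-size arithmetic.  Includes a synthetic genome
    pair simulator with planted insertions, inversions and repeat arrays
    that provides ground truth for every detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
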