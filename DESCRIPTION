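Package: septalink
Title: Gene-Neighborhood Linkage, Muropeptide Mass Assignment and Septal
    Fluorescence Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three desk-scale analyses used when characterising
    septal peptidoglycan hydrolases and their regulators in bacteria.
    Classifies genes into families by PFAM/KEGG/TIGRFAM annotation rules and
    quantifies cross-genome co-occurrence, strand concordance and intergenic
    distance of two families (with iTOL dataset export along a phylogenetic
    tree); computes elemental formulas, monoisotopic masses and m/z of
    peptidoglycan glycan fragments, assigns LC-MS peaks at ppm tolerance,
    detects N-deacetylation by the 42.0106 Da acetyl mass shift and
    quantifies relative HPLC peak areas; and, from fluorescence images plus
    integer label masks, extracts per-cell medial axes, axial intensity
    profiles, demographs, morphometrics and a midcell-minus-quarter
    intensity statistic with control-median normalization and nonparametric
    group comparison. Seeded synthetic-data generators (annotated genomes
    with planted operon linkage, rod-shaped cells with a planted septal
    band, LC-MS peak lists and assay area tables) accompany each analysis
    and record machine-readable ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    EBImage,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
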