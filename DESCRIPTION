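Package: necropop
Title: Biocultural Population Structure of Iron Age Necropolises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unravelling the population structure of necropolis
    assemblages from three independent lines of evidence: strontium isotope
    ratios (87Sr/86Sr) of tooth enamel and bone for local/non-local provenance
    and intra-individual mobility typing; non-metric dental trait frequencies
    for biodistance via the Freeman-Tukey-corrected Mean Measure of Divergence
    with multidimensional scaling and Ward clustering; and binary grave-good
    matrices analysed with Jaccard distances, complete-linkage clustering,
    contingency chi-square, distance-matrix AMOVA with permutation Phi-ST,
    correspondence analysis, Random-Forest variable importance and stepwise
    VIF selection.  A synthetic-necropolis generator with known ground truth
    supports end-to-end testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    MASS
Config/testthat/edition: 3
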