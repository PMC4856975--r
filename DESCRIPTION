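Package: bundlekit
Title: Sequence Bundles and Explorative Analysis of Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-aggregative visualization of multiple sequence alignments
    as sequence bundles (stacked semi-opaque Bezier threads through a
    symbol-by-position grid, exported as SVG or PNG), together with an
    explorative analysis toolkit: a boolean-regex selection query language,
    profile-HMM Fisher-score embeddings, correspondence analysis of
    sequences and site-residue categories, per-site classifier screens for
    specificity-determining sites, exact binomial covariation tests,
    substitution-matrix kernel distances with neighbour-joining trees,
    spectral clustering, and synapomorphy/homoplasy annotation of sequence
    motifs on a tree. Includes deterministic generators for toy and
    planted-structure alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    e1071,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    MASS,
    jsonlite,
    png,
    withr
Config/testthat/edition: 3
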