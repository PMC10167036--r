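Package: hgonet
Title: Coexpression Screening and Reversible Kinetics of the
    Geranylhydroquinone Oxidoreductase Branch Point
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational workflow behind the discovery and
    characterization of AeHGO, the geranylhydroquinone 3''-oxidoreductase
    that controls the branch point between shikonin and shikonofuran
    biosynthesis. Implements the coexpression-based candidate-gene screen
    (abundance filtering, fuzzy c-means temporal clustering with
    membership-core assignment, marker-guided cluster selection, and exact
    local-alignment homology filtering), Michaelis-Menten and
    substrate-inhibition kinetics with identifiability diagnostics and the
    unit arithmetic linking Vmax, kcat and catalytic efficiency, a
    thermodynamically consistent kinetic model of the reversible
    three-compound reaction network with NADP(H) recycling, cofactor
    channeling and a competing cofactor sink, monoisotopic mass utilities,
    and synthetic-data generators that plant recoverable ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    deSolve,
    graphics,
    methods,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
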