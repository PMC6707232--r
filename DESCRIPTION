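Package: xlhdx
Title: Integrative Cross-Linking and Hydrogen-Deuterium Exchange Mass
    Spectrometry Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for integrative structural mass spectrometry of
    multi-subunit protein complexes. Builds one-bead-per-residue
    coarse-grained models from PDB/mmCIF coordinates, maps chemical
    cross-links (e.g. BS3 lysine-lysine links) onto models as upper-bound
    distance restraints, scores restraint satisfaction and two-conformer
    exclusive-satisfaction ensembles, and places mobile rigid bodies onto a
    stationary scaffold by Metropolis Monte-Carlo minimisation of restraint
    violations with excluded volume. Fits deuterium-uptake titrations
    (PLIMSTEX) with an exact 1:1 mass-balance binding model to estimate
    local dissociation constants, and classifies differential HDX-MS
    uptake tables with a blanket confidence-interval significance filter
    (Woods-plot semantics). Includes a synthetic-data generator producing
    toy complexes, cross-link tables, titrations and replicate uptake
    tables with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
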