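Package: rotasuite
Title: Classification of RNA Backbone Suite Rotamers from Ribose 13C'
    Chemical Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how far ribose 13C' chemical shifts (C1'-C5')
    can classify RNA backbone suites into the 46 consensus rotamers and
    into coarser rotamer families. Includes a packaged rotamer catalog and
    family grouping schemes, backbone dihedral computation and suite
    extraction from PDB/mmCIF structures, nearest-rotamer assignment, a
    rigid-geometry Monte-Carlo conformer sampler with clash elimination and
    Shannon-entropy based subsample-size selection, a synthetic isotropic
    shielding generator standing in for quantum-chemical data, shielding to
    shift referencing with simple and effective reference schemes, rotamer
    substitution matrices (ROSUM) with weighted-accuracy scoring, and
    leave-one-out and train/test classification regimes over several
    classifier types with a random baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    class,
    e1071,
    igraph,
    jsonlite,
    nnet,
    randomForest,
    rpart,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
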