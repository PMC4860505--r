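Package: fiberglow
Title: Single-Molecule DNA Fiber Analysis of Tagged Psoralen Crosslinks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and image analysis of single-molecule DNA fiber
    assays in which digoxigenin-tagged trimethylpsoralen (Dig-TMP)
    interstrand crosslinks are detected on stretched DNA fibers by
    immuno-quantum-dot microscopy. Generates ground-truth fiber
    populations carrying psoralen adducts and nascent replication
    tracts, renders them as multi-channel fluorescence images, traces
    fibers, detects quantum-dot spots and replication tracts, and
    reproduces the assay's summary statistics: the fraction of fibers
    with a signal, adduct density per 1000 kb, inter-adduct spacing
    distributions, and the single- versus double-sided classification
    of replication-fork encounters with crosslinks, together with the
    associated chi-squared, t and z tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
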