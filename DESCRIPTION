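Package: icebound
Title: Bound-Water Network Analysis at Antifreeze Protein Ice-Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the semi-ordered water networks that
    antifreeze proteins (AFPs) organize on their ice-binding sites (IBS).
    Reads protein crystal structures (PDB/mmCIF), expands crystallographic
    symmetry to surround the IBS with equivalent waters, and extracts the
    recurring hydration motifs of microbial beta-helical AFPs: zigzag water
    chains with their spacing and angle statistics, linear water troughs along
    hydrophobic grooves, and ring-like hydrophobic hydration shells. Generates
    ideal hexagonal-ice (ice Ih) oxygen lattices, extracts basal and prism
    plane patches, and rigidly docks bound-water sets onto them by
    correspondence-searching iterative closest point registration built on the
    Kabsch algorithm. Also includes a circular-dichroism fraction-unfolded and
    melting-midpoint estimator and a hydrogen-bond forward-lifetime residence
    time statistic for trajectory event tables, plus seeded synthetic-data
    generators for every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    clue,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
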