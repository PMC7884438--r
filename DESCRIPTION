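Package: pigmentnet
Title: Pigment Networks and Energy-Transfer Pathway Analysis for
    Photosystem Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural analysis of pigment-protein supercomplexes such as
    photosystem I with its light-harvesting antenna (PSI-LHCI). Reads
    macromolecular coordinate files (mmCIF/PDB), classifies chlorophyll,
    carotenoid and lipid cofactors, computes edge-to-edge distances between
    conjugated pi systems, detects the protein residues that axially
    coordinate each chlorophyll's central magnesium, builds
    distance-thresholded pigment adjacency graphs and enumerates plausible
    excitation energy-transfer pathways from the antenna belt to the core,
    and compares pigment organisation between homologous structures after
    core-based rigid-body superposition. Includes a deterministic synthetic
    structure generator with fully known geometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
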