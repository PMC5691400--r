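Package: gausscavity
Title: Protein Cavity Detection Between Two Gaussian Molecular Surfaces
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric detection of protein surface cavities (putative
    ligand-binding pockets) on a regular voxel grid. Two implicit Gaussian
    molecular surfaces are built from the atomic coordinates: an inner
    surface from the van der Waals radii and an outer surface from radii
    inflated by a water-probe radius. Voxels lying entirely between the two
    surfaces are classified through per-corner isovalue flags, filtered by a
    3x3x3 neighbourhood condition guaranteeing room for a water molecule,
    and aggregated into cavities with DBSCAN clustering. Includes PDB input
    via 'bio3d', synthetic molecule generators with brute-force oracles for
    validation, a ground-truth benchmarking layer (greedy centre matching,
    distance bins, sensitivity/specificity/accuracy metrics), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
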