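Package: alexpr
Title: Coordinate-Based Meta-Analysis of Grey-Matter Alteration Linked to
    Spatial Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An imaging-transcriptomics pipeline: anatomical likelihood
    estimation (ALE) coordinate-based meta-analysis of voxel-based
    morphometry foci, construction of voxel-wise gene-expression volumes
    from donor point samples by Voronoi tessellation, cluster-wise
    correlation between the ALE Z map and each gene map, and a
    cluster-permutation Monte Carlo test of network-level gene-alteration
    association on a resting-state network atlas.  Includes synthetic-data
    generators with known ground truth for validation, NIfTI input/output,
    Sleuth-style and CSV foci parsing, and MNI-to-Talairach coordinate
    conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
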