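Package: procv
Title: Protein Pocket Recognition from 3D Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structure-based recognition of protein binding pockets by
    point-cloud matching. Protein and ligand structures are converted to
    3D point clouds, keypoints are detected by grid-centroid uniform
    sampling, pocket-to-protein correspondences are found by KD-tree
    nearest-neighbour search over local angular-histogram descriptors,
    and consistent correspondences are grouped by 3D Hough voting with
    rigid-transform estimation. Includes PDB and PCD (Point Cloud Data)
    readers and writers, a controlled coordinate-noise model, pocket
    overlap and confusion-based evaluation metrics (POS, F1, MCC, RMSE),
    and a deterministic generator of protein-like synthetic structures
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
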