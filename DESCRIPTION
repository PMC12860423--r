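Package: sammri
Title: Region-Level Agnostic and Voxelwise Parametric Mapping for Structural MRI under Permutation Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-arm statistical mapping for multi-site grey-matter probability
    maps. The region-level arm trains a per-region classifier (t-test voxel
    selection, one-component partial least squares, linear support vector
    machine) and declares significance from a concentration-inequality
    worst-case accuracy bound; the voxelwise arm runs a two-sample t-map with
    Gaussian smoothing, a cluster-forming threshold and permutation-based
    cluster-level family-wise error correction. Both arms plug into a
    subsampling engine that estimates per-region probability-of-detection and
    false-positive maps under case-control and control-control designs, with
    permutation p-values. Includes a synthetic multi-site cohort generator
    with planted effects, site offsets and corrupted-scan injection, plus the
    quality-control rule that excludes failed scans.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
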