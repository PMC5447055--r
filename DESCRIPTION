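Package: tractparc
Title: Connectivity-Based Brain Parcellation via Normalized-Cut Spectral
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for tractography-based brain
    parcellation. Per-seed-voxel whole-brain streamline-count profiles are
    thresholded, corrected for path-length bias, and down-sampled into a
    native connectivity matrix; the cross-correlation matrix between seed
    profiles is partitioned with normalized-cut spectral clustering over a
    range of cluster counts. Individual parcellations are harmonized across
    subjects (and hemispheres) by optimal label assignment, summarized as
    probabilistic maps and maximum probability maps with 26-neighbor
    tie-breaking and 6-connected noise correction, and scored with a full
    cluster-validity suite (Cramer's V, Dice, normalized mutual information,
    variation of information, silhouette, continuity, hierarchy index,
    topological distance) under split-half, pairwise, and leave-one-out
    resampling, yielding a majority-vote suggestion for the number of
    subregions. A synthetic-cohort generator with planted subregions makes
    the whole pipeline testable without diffusion MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
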