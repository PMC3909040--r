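Package: mesoconn
Title: Seed-Based Midbrain-Striatal Resting-State Connectivity with
    Inverted-U Drug-by-Span Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for identifying putatively dopaminergic midbrain-striatal
    pathways in resting-state fMRI. Implements seed-based Fisher-z
    connectivity mapping, temporal band-pass filtering, Gaussian spatial
    smoothing, white-matter/CSF nuisance regression, voxelwise group
    inference with a quadratic (inverted-U) drug-by-working-memory-span
    interaction contrast, Benjamini-Hochberg FDR with small-volume and
    cluster-extent thresholding, and Venn-style voxel-set overlap analysis
    with chi-square proportion tests. A seeded synthetic BOLD phantom
    generator with planted ground-truth connectivity supports end-to-end
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
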