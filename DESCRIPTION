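Package: cortexqmr
Title: Quantitative MRI Characterization of Cortical Demyelination on a
    Synthetic Fixed-Hemisphere Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-simulates the four quantitative MR acquisitions of a
    post-mortem multiple sclerosis imaging protocol (variable flip angle SPGR
    for T1/M0, balanced SSFP for T2, a magnetization-transfer SPGR pair for
    MTR, and a double-angle pair for B1 mapping) on a synthetic folded
    fixed-hemisphere phantom with type III subpial cortical lesions and focal
    white matter lesions, inverts them back to quantitative maps with B1
    correction, quantifies myelin content from synthetic chromogen-stained
    histology slides, registers histology to the MR frame with tag-point
    affine transforms, samples the cortex at fixed laminar depths, and
    reproduces the voxel-wise statistical comparison of cortical lesions
    against normal-appearing cortex (per-tissue summaries, Bonferroni
    corrected t-tests, Pearson and Spearman correlations with myelin content,
    and normalized histograms).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
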