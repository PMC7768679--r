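Package: facetract
Title: Cross-Modal PCA Reconstruction of Paired Face and Vocal-Tract Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers the configuration of one imaged modality (midsagittal
    vocal-tract MR sequences) from another (frontal face video) by principal
    component analysis of hybrid texture-plus-warp representations. Each matched
    frame is serialized as its pixel values concatenated with a dense optic-flow
    warp field onto a reference frame; the two modalities are stacked into a
    hybrid observation-by-frame array and decomposed by uncentered PCA. Zeroing
    one modality's block before projection reconstructs it from the other, with
    fidelity scored by the correlation and sum of squared errors between original
    and reconstructed loadings. Includes frame-rate matching between sequences,
    iterative mean-texture reference-frame selection, frame-order permutation
    nulls (single-frame and paired-frame variants), Bubbles occlusion-importance
    mapping, and a synthetic paired-sequence generator with ground-truth shared
    latent causes for validating every stage without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    png,
    yaml,
    jsonlite,
    ggplot2,
    tibble,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
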