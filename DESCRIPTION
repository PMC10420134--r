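Package: marrowtex
Title: Vertebral Bone-Marrow Texture Radiomics and Annular-Fissure Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to associate three-dimensional texture patterns in lumbar
    vertebral bone marrow (paired T1- and T2-weighted MRI) with outer annular
    fissures in the adjacent intervertebral disc. Implements isotropic
    resampling, volume normalization with +/-3 SD truncation and
    fixed-bin-width discretization; a 93-feature-per-modality catalog of
    first-order, GLCM, GLRLM, GLSZM, GLDM and NGTDM features;
    feature-robustness screening via ICC(1,1) under segmentation contraction
    and voxel-size perturbation; correlation pruning; sequential backward
    feature selection under 5-fold cross-validated balanced accuracy with
    multilayer-perceptron, random-forest and k-nearest-neighbour models;
    backward-elimination logistic regression with odds-ratio reporting; ROC
    analysis; and a mid-p McNemar comparison of the radiomic classifier
    against Modic changes as a marker. Includes a seeded synthetic-cohort
    generator of paired vertebral volumes, masks and labels so the full
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    ranger,
    class,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
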