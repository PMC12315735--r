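Package: alecontrast
Title: Activation Likelihood Estimation Meta-Analyses and Meta-Analytic Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-based meta-analysis of neuroimaging activation foci using
    the activation likelihood estimation (ALE) algorithm, with cluster-level
    family-wise error correction by permutation, meta-analytic contrast analysis
    between two ALE meta-analyses via a pool-shuffle-split permutation null, and
    voxel-, cluster- and peak-level similarity metrics for comparing thresholded
    statistical brain maps. Includes a synthetic coordinate-data generator with
    known ground-truth convergence centres so that the whole pipeline can be
    exercised and calibrated without access to proprietary coordinate datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
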