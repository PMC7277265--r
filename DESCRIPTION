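Package: roimvpa
Title: ROI-Based Multivariate Pattern Decoding, Informational Connectivity
    and Encoding Models for Event-Related fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for region-of-interest multivariate pattern analysis of
    event-related fMRI. Implements trial-example extraction from run-wise
    normalized BOLD time series, binary category decoding with a PCA plus
    linear support-vector-machine pipeline under stratified-shuffle,
    leave-one-run-out and out-of-sample word-pair cross-validation,
    informational connectivity from leave-one-trial-out discriminability
    time series with a permutation effect size that is independent of the
    classification level, voxelwise ridge-regression encoding models scored
    by cross-validated variance explained with an empirical chance estimate,
    representational dissimilarity matrices, and group-level statistics with
    false-discovery-rate control. A synthetic-data generator emulates the
    event-related design (pseudo-exponential inter-trial jitter, condition
    dependent multivoxel signal gain, cross-region discriminability
    coupling, haemodynamic convolution, drift and noise) so every stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
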