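Package: brainsig
Title: Whole-Brain Multivariate Signatures Predicting Subjective Ratings
    from fMRI Activation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains and evaluates whole-brain multivariate "signatures"
    that predict trial-wise subjective ratings (for example anxious
    arousal during uncertain-threat anticipation) from fMRI activation
    maps. Covers first-level GLM beta estimation with a canonical
    double-gamma HRF, linear support vector regression on gray-matter
    masked voxel patterns, participant-grouped repeated cross-validation,
    permutation and bootstrap inference on prediction performance and
    voxel weight maps, forced-choice classification, Haufe
    structure-coefficient encoding maps with positive conjunctions,
    cross-signature comparison (cross-prediction, spatial correlation,
    ROI cosine profiles), region-restricted and random-voxel-subsampling
    analyses, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
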