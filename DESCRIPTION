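Package: emfdd
Title: Emotional Modulation Function Signatures for Developmental Disorder
    Recognition from Child Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how a child modulates utterance-level acoustic features
    with the emotional valence of speech, and uses the per-subject modulation
    signature -- the coefficient vector of a multilinear regression of
    per-valence feature moments onto the valence scale -- to discriminate
    children with developmental disorders from typically developing children.
    Provides per-subject valence-correlated feature selection with redundancy
    pruning, per-valence moment matrices (mean, skewness, kurtosis), the
    minimum-norm modulation-coefficient fit, a test-sample-conditioned dynamic
    feature-selection cascade (Fisher score, Mahalanobis ratio, Gaussian class
    probability), leave-one-subject-out linear-SVM evaluation with full metric
    reporting, utterance-level standard-paradigm baselines, and a synthetic
    cohort generator with planted modulation effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    e1071,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
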