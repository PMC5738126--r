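Package: gendernet
Title: Gender Differences in Multiplex Social Networks of a Student Cohort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for studying gender differences in a densely
    instrumented student cohort: subsampled pooled-SD effect sizes for
    personality, mobility and network indicators; location and interaction
    entropy; gender-label permutation null models yielding z-scores and
    permutation p-values for dyad and triad homophily motifs on proximity,
    online and telecommunication networks; overlap-distance
    k-nearest-neighbour imputation of missing behavioural features; and a
    cross-validated, imbalance-aware gender classification stage with
    feature-importance ranking. Includes a synthetic cohort generator with
    planted effect sizes and homophily so every stage is testable end to end
    without access to any private cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    e1071,
    xgboost,
    rpart,
    caret,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
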