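Package: pshtraj
Title: Trajectory Phenotyping of Sympathetic Hyperactivity After
    Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores daily severity of paroxysmal sympathetic
    hyperactivity from electronic-health-record vital-sign streams using
    the Clinical Feature Scale (CFS) of the PSH Assessment Measure,
    groups 13-day CFS trajectories by K-means clustering under a dynamic
    time warping distance with DTW barycenter averaging and elbow-based
    model selection, and relates trajectory groups to in-hospital
    outcomes and admission predictors via contingency tests, one-way
    analysis of variance and forward-stepwise multinomial logistic
    regression.  A synthetic-cohort generator emulates the data
    structure of an acute traumatic-brain-injury cohort so the whole
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nnet,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
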