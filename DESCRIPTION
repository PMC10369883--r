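Package: spit
Title: Differential Transcript Usage Detection in Heterogeneous Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects differential transcript usage (DTU) in RNA-Seq cohorts
    where the case population may be heterogeneous, i.e. composed of
    undetermined subgroups ("splicotypes") that carry distinct sets of
    isoform-switching events. Transcript counts are transformed to isoform
    fractions, case samples are partitioned per transcript with a Gaussian
    kernel density estimate, tails are compared to controls with
    Mann-Whitney U tests, and significance is judged against an empirical
    null distribution of minimal p-values built by repeatedly splitting the
    control group in half. Candidate events explainable by a covariate are
    removed with depth-one random-forest permutation importance, and case
    samples are clustered on the resulting binary event matrix. A bundled
    simulator generates ground-truth heterogeneous DTU datasets, and a
    leave-one-out cross-validation routine fits the bandwidth and threshold
    hyperparameters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
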