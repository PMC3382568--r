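Package: stutterMVPA
Title: Trial-Wise Multivoxel Pattern Classification of Stuttering Symptom
    Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to separate more-typical (MT) from less-typical (LT)
    stuttering symptoms by trial-wise multivoxel pattern analysis of
    sparse-sampling event-related fMRI, and to assign monosyllabic
    whole-word repetitions (WWR) to one of those types.  Includes a seeded
    synthetic-cohort generator with planted region effects, symptom-code
    trial labelling, percent-signal-change preprocessing, a linear
    soft-margin support vector machine trained by SMO, whole-brain
    discrimination mapping with group t-statistics, Monte-Carlo
    cluster-size correction, leave-one-trial-out validation, and
    condition-wise BOLD comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
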