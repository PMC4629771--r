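Package: twinkin
Title: Classical Twin Analysis for Binary and Continuous Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Variance-component analysis of twin-pair data under the
    classical twin design. Provides probandwise concordance rates,
    double-entry intraclass and tetrachoric (liability-scale)
    correlations, maximum-likelihood ACE/ADE/AE/CE/DE/E model fitting for
    continuous and binary traits, bivariate Cholesky decomposition with
    genetic and environmental correlations, a direction-of-causation
    model comparison, and co-twin control (matched discordant-pair)
    analysis. Includes a synthetic twin-cohort generator with
    liability-threshold binary traits, questionnaire misclassification
    and proband ascertainment, plus a catalogue of seeded
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), mvtnorm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
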