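Package: headingbias
Title: Bias and Precision in Visual and Vestibular Heading Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for systematic biases in human heading
    estimation in the earth-horizontal plane.  Reduces heading
    identification trial logs to per-heading bias and variability curves
    using circular statistics with Chauvenet outlier exclusion, runs and
    analyses adaptive up-down staircase discrimination experiments with
    cumulative-Gaussian psychometric fits (PSE/JND), predicts heading bias
    by population-vector decoding of direction-tuned neural populations
    (including an otolith-afferent gravito-inertial firing model), and
    fits a Bayesian observer with a bimodal lateral prior to observed bias
    curves.  Seeded synthetic-data generators for observers, experiment
    designs, motion profiles and neural populations make the full pipeline
    exercisable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
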