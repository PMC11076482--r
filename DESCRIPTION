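Package: catscout
Title: Gaussian-Process Surrogate Screening of Triarylborane Catalysts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: In-silico-assisted optimisation of triarylborane catalysts for
    frustrated-Lewis-pair reductive alkylation. DFT-derived descriptor pairs
    (Lewis-acidity and deformation-energy proxies) feed Gaussian-process
    surrogate models of catalytic turnover frequency; leave-one-out Q2
    cross-validation selects among candidate descriptor-pair models; virtual
    library prediction, cross-model disagreement detection and experimental
    update steps identify the optimal borane. Includes a seeded
    synthetic-data generator with known ground truth for end-to-end
    validation of the screening campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
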