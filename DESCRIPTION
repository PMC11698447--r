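Package: occultsim
Title: Microsimulation of Lung Cancer Natural History, Occult Metastasis and
    CT Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level microsimulation of non-small-cell lung cancer:
    smoking-driven tumor onset via a two-stage clonal expansion model,
    exponential primary growth with a Gamma-distributed growth rate,
    volume-indexed nodal and distant metastatic seeding, symptomatic
    detection through a volume-linear hazard with stage-dependent offsets,
    and low-dose CT screening under configurable eligibility policies.
    Tracks occult (seeded but sub-detectable) metastases, maps detected
    disease to stage groups, samples post-diagnosis survival from
    mixture-cure curves by inversion, and estimates screening mortality
    reduction on counterfactually paired simulated arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
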