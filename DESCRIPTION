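Package: rvpower
Title: Power and Type I Error Simulation for Rare-Variant Burden and
    SKAT Association Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates case-control cohorts of independent rare variants
    under a logistic penetrance model with exact prevalence calibration,
    and estimates type I error and power of region-based rare-variant
    association tests across balanced and unbalanced study designs. Two
    tests are implemented on Madsen-Browning weighted genotype bins: a
    weighted burden test (logistic regression likelihood-ratio test) and
    the sequence kernel association test (SKAT) with a
    mixture-of-chi-squares p-value computed by characteristic-function
    inversion with a moment-matching fallback. Includes a scenario-grid
    replicate engine, VCF/TSV import and export of simulated cohorts,
    and permutation oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
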