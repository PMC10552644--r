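Package: psorqsp
Title: Virtual-Trial Simulation of Certolizumab Pegol in Moderate-to-Severe
    Psoriasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A quantitative systems pharmacology toolkit for simulating a
    two-arm virtual clinical trial of certolizumab pegol in
    moderate-to-severe plaque psoriasis. Generates virtual populations
    matching published trial demographics, simulates individualized
    two-compartment (skin depot to blood) pharmacokinetic models of
    subcutaneous dosing regimens, scores predicted protein activity with
    the tSignal statistic and calibrates it against clinical efficacy,
    clusters patient-level mechanistic outputs with stability diagnostics,
    and summarizes cluster-differential proteins by hypergeometric
    enrichment linked over a protein network with a modified Hausdorff
    distance. A synthetic protein-activity generator stands in for
    proprietary network-propagation outputs so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    cluster,
    class,
    mclust,
    kernlab,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
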