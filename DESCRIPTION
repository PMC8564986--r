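Package: screencea
Title: Cost-Effectiveness of Annual Screening Mammography via a Multistate Markov Cohort Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus five-state Markov cohort simulation for the
    cost-effectiveness of annual screening mammography under mixed
    government/private provider pricing, with discounted cost and life-year
    accounting, ICER / incremental net monetary benefit / deaths-averted
    metrics, one-way (tornado) sensitivity analysis, second-order Monte Carlo
    probabilistic sensitivity analysis with Beta/Gamma/Dirichlet parameter
    distributions, and an individual-level microsimulation used as a
    brute-force oracle for the cohort engine. Ships a baseline scenario for
    an Ethiopian screening cohort and a generator of random valid scenarios
    for property testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
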