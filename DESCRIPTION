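Package: psisim
Title: Portfolio Simulation of Health Priority Setting Institutions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo portfolio simulation quantifying the value of an
    explicit health priority setting institution (PSI). Candidate health
    interventions are sampled as correlated log-normal (cost, benefit) pairs
    with an independent log-normal impacted-population size, funding rules
    based on a cost-effectiveness-ratio threshold (optionally with a budget
    limit, limited analysis capacity, or a phased run-in) are compared
    against first-come-first-served counterfactuals on identical candidate
    sets, and paired outcomes are summarised as total costs, total health
    benefits, net health benefit and incremental cost-effectiveness ratios.
    Ships indicative parameterisations for an established (UK-like) and a
    fledgling (Malawi-like) universal health coverage setting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
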