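Package: cascade
Title: Expected-Value Decision Analysis for Complex Wound Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decision-analytic toolkit for choosing between routine closure
    and definitive reconstruction of complex wounds on expected total episode
    cost grounds. Provides an additive Clinical Risk Score with four-tier
    stratification and applicability gating, tier-conditional failure
    probability ranges and failure cost tiers with bound-policy resolution,
    the incremental-cost decision rule (reconstruction favored when the
    incremental reconstruction cost is below the absolute risk reduction
    times the failure trajectory cost), deterministic one-way and two-way
    threshold grids, seeded Monte Carlo probabilistic sensitivity analysis,
    cohort-level avoided-cost-exposure and institutional exposure modeling,
    a seeded synthetic case generator, and schema-validated JSON/YAML case
    files with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
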