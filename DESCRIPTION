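Package: traconsumer
Title: Screening-Level Consumer Chemical Exposure Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic screening-tier (Tier 1) estimation of consumer
    inhalation, dermal and oral exposure to substances in products and
    articles. Implements vapor-pressure band release fractions with a
    saturated-vapor-concentration cap for inhalation, a thickness-layer model
    for dermal contact, and ingested-amount models for the oral route,
    together with the comparator models commonly used to benchmark them:
    a ventilated well-mixed-room box model, a mass-transfer evaporation
    simulator, semi-infinite-slab diffusion emission from articles,
    article mass-balance and migration-based approaches, and
    mouthing-time inversions for mouthed articles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
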