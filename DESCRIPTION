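Package: fishstatus
Title: Ensemble Assessment of Global Fish Stock Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Aggregates per-stock biomass (B/BMSY) and exploitation-rate
    (U/UMSY) time series from scientific stock assessments into global
    status trajectories. Implements an ensemble of ten diagnostics (five
    statistical averaging methods, including a hierarchical state-space
    random-walk smoother, crossed with two rebuilding-target definitions),
    Kobe-plot status classification, recent trend slopes, and
    proportion-within-target series, together with a surplus-production
    simulator of assessed-stock panels so the whole pipeline can be
    exercised with known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    ggplot2,
    graphics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
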