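Package: hflf
Title: High:Low Frequency Spectral Power Ratios for REM Sleep Without Atonia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies phasic REM sleep without atonia (RSWA) in chin
    (mentalis) surface EMG recorded during polysomnography, using the ratio
    of high-frequency (20-55 Hz) to low-frequency (2-20 Hz) spectral power
    computed each second from Welch power spectral densities on 2 s sliding
    windows. Provides EDF, hypnogram and event-table input handling with
    record-level eligibility screening, per-second absolute and relative
    spectra on a 0.5 Hz grid, epoch-based (E1/E2/E3) and window-based
    (W1/W2) grouping of the ratio against visually scored phasic events,
    median relative-spectrum crossover estimation, the associated inferential
    statistics (one-way ANOVA with Tukey HSD, Welch t, variance-ratio F),
    a synthetic polysomnography generator for validation, and an end-to-end
    pipeline with structured JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
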