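Package: gnrhpulse
Title: Pulsatile GnRH Signalling Simulation and Information Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mechanistic simulation of pulsatile gonadotropin-releasing
    hormone (GnRH) signalling in pituitary gonadotropes. Provides square-wave
    pulse protocols with exact input integrals and compensated protocol
    families; a minimal Michaelis-Menten pulse-decoding cascade (one fast
    effector activating fast and slow downstream effectors); a
    receptor-network ODE model with agonist-induced receptor internalization
    and recycling, phospholipase C, cytoplasmic calcium, nuclear ppERK,
    NFAT nucleocytoplasmic cycling and Egr1 induction; transcriptional logic
    gates (single-input, AND, OR and a sequential co-operative promoter)
    driving a reporter; frequency-, dose- and internalization-scan analyses
    with area-under-curve readouts, optimal-period identification and
    monotonic-versus-bell shape classification; and single-cell tools that
    simulate log-normal cell-to-cell parameter variability and estimate the
    mutual information between stimulus level and single-cell response.
    All analysis functions return tidy tibbles and ggplot2 visualisations
    are provided via autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    patchwork,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
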