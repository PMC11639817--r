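Package: amaresr
Title: Time-Domain AMARES Fitting of Magnetic Resonance Spectroscopy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies magnetic resonance spectroscopy (MRS) free induction
    decays (FIDs) by the AMARES method: model-based time-domain fitting of a
    sum of exponentially damped sinusoids under spreadsheet-encoded prior
    knowledge (initial values, box bounds, and algebraic ties between peak
    parameters such as J-coupling splittings and amplitude ratios). Includes
    Hankel singular value decomposition (HSVD) and Levenberg-Marquardt
    initializers, bounded nonlinear least-squares fitting with pluggable
    time-domain, frequency-masked, and user-defined objectives, FIR-based
    frequency-selective extraction, Cramer-Rao lower bound uncertainty with
    propagation through linear parameter ties, per-peak signal-to-noise
    ratios, multiplet result aggregation, metabolite-residual removal for
    macromolecule spectra, parallel batch fitting, and a Monte-Carlo
    validation harness.
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
    minpack.lm,
    parallel,
    pracma,
    purrr,
    readxl,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
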