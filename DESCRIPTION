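Package: vocompare
Title: Method Comparison for Untargeted GC-MS Volatile Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds per-method consensus compound profiles ("RT ranges") from
    replicate GC-MS peak tables of body-odor samples, filters them against
    procedural blanks, assigns tentative identities by NIST-style spectral
    match factors, classifies compound volatility (boiling point threshold
    250 C) and origin (exogenous, potentially endogenous, potentially
    metabolized), aligns compounds across instruments via elution order plus
    diagnostic fragment ions, and compares sampling methods statistically
    (Spearman rank correlations with exact permutation p-values, and a
    linear mixed model with likelihood-ratio test for common-versus-unique
    abundance). Includes a synthetic peak-table generator that emulates a
    multi-adsorbent marmoset body-odor study design so the whole pipeline is
    testable without raw chromatograms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
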