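Package: craniospinal
Title: Craniospinal Compliance from Cerebral Arterial Flow and Lumbar
    Infusion Recordings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates arterial-related craniospinal compliance under
    physiological conditions by combining cine phase-contrast MRI arterial
    flow curves with the intracranial pressure pulse extracted from baseline
    lumbar recordings, and compares it with the compliance-related parameter
    derived from constant-rate lumbar infusion tests. Provides the full
    per-subject pipeline (arterial volume-change amplitude, FFT-filtered
    ensemble-averaged ICP pulse amplitude, plateau detection, CSF outflow
    resistance), cohort-level nonparametric statistics with Holm correction
    and Spearman correlation matrices, and a seeded synthetic-cohort
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
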