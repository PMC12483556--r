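Package: gardose
Title: Genomic Adjusted Radiation Dose Modeling and In Silico Radiotherapy Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for personalizing radiotherapy dose from tumor gene
    expression. Computes the radiosensitivity index (RSI) from a 10-gene
    rank-based signature, derives the patient-specific linear-quadratic
    coefficient alpha_g, and combines it with the delivered fractionation to
    obtain the genomic adjusted radiation dose (GARD) and EQD2. Provides the
    survival machinery needed for GARD analyses (Kaplan-Meier, log-rank,
    Cox proportional hazards, maximally selected log-rank cut-points,
    censored Weibull fits, and IPCW time-dependent AUC), an in silico
    clinical-trial simulator for unselected, GARD-selected and personalized
    iso-GARD dose de-escalation designs, and a calibrated synthetic-cohort
    generator emulating an HPV-positive oropharyngeal cancer population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
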