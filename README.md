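# gardose

Genomic adjusted radiation dose (GARD) modeling for personalized
radiotherapy, with in silico dose de-escalation trials.

## What this is for

Radiotherapy doses are prescribed almost uniformly — e.g. 70 Gy in 35
fractions for HPV-positive oropharyngeal cancer — yet tumors differ widely
in intrinsic radiosensitivity. `gardose` implements the GARD framework for
analysts studying dose personalization and de-escalation: it converts a
tumor's gene-expression radiosensitivity index (RSI) into the
patient-specific linear-quadratic coefficient

    alpha_g = -ln(RSI) / (n d) - beta d        (n = 1, d = 2 Gy, beta = 0.05 / Gy^2)

and combines it with the delivered fractionation (n_c fractions of d_c Gy)
into the genomic adjusted radiation dose

    GARD = n_c d_c (alpha_g + beta d_c),

a dimensionless predicted treatment effect (at 2 Gy/fraction, exactly
`-n_c ln RSI`). On top of this dose algebra the package provides:

- **Signature scoring** — RSI from an expression matrix via the published
  10-gene rank-based signature (`score_rsi()`, `rsi_signature()`).
- **Survival analysis** — Kaplan-Meier and Cox wrappers, a two-sample
  log-rank statistic, a maximally selected log-rank cut-point scan with
  optional permutation-adjusted inference, censored Weibull fits, and an
  IPCW time-dependent AUC (`optimal_cutpoint()`, `fit_weibull()`,
  `td_auc_ipcw()`, ...).
- **In silico trials** — smoothed-bootstrap virtual patients and three
  designs: unselected de-escalation (70 vs 60 Gy), GARD-selected
  de-escalation, and personalized iso-GARD dosing
  (`run_unselected_deescalation_trial()`, `run_gard_selected_trial()`,
  `run_personalized_iso_gard()`).
- **Synthetic cohorts** — a calibrated generator reproducing the published
  population structure (GARD median 39.1, IQR 12.6; 94.1% OS at 36 months,
  87.3% at 60; censoring at 60 months), so the whole pipeline is testable
  without restricted patient data (`cohort_spec()`, `generate_cohort()`).
- **Orchestration** — `run_pipeline()` runs the full analysis sequence on
  any cohort table and writes JSON/CSV reports; `inst/cli/gardose.R` is a
  thin command-line front end.

## Worked example

```r
library(gardose)

# a 191-patient synthetic cohort with the study's population structure
cohort <- generate_cohort(cohort_spec(n = 191, seed = 17))

fit_cox(cohort, "gard")
#> Cox proportional hazards (ties = efron ): n = 191 , events = 18
#>  term estimate      se     hr conf_low conf_high  p_value
#>  gard -0.07998 0.02975 0.9231   0.8708    0.9786 0.007178

optimal_cutpoint(cohort$time_months, cohort$event, cohort$gard,
                 n_perm = 1000, seed = 1)
#> Maximally selected log-rank cut point
#>   cut: marker >= 41.48 (n_high = 75, n_low = 116)
#>   |z| = 3.569, naive p = 0.0003578, permutation-adjusted p = 0.01598 (1000 permutations)

run_personalized_iso_gard(cohort, target_gard = 32)
#> Personalized iso-GARD prescription report (target GARD = 32 )
#>   patients: 191 (0 with unreachable target)
#>   mean fractions spared vs reference: 4.55
#>   underdosed at delivered plan: 23.0%; requiring 60-70 Gy: 20.9%
```

Each unit of GARD lowers the hazard (HR 0.92 here), the data-driven cut
point lands next to the planted risk change at GARD 42, and prescribing
every patient the minimum dose reaching GARD 32 spares about 4.5 fractions
per patient on average while flagging the ~21% of patients who genuinely
need 60–70 Gy — the subgroup that uniform de-escalation to 60 Gy would
underdose.

The inverse dose solver reproduces the published personalized-dose extremes
from the delivered-GARD extremes at standard dosing:

```r
a <- alpha_g_from_gard(c(71.7, 19.7), fx_schedule(35, 2))
dose_for_target_gard(a, target_gard = 32)[, c("required_dose_continuous",
                                              "required_dose_gy")]
#>   required_dose_continuous required_dose_gy
#> 1                 31.24128               31
#> 2                113.70558              113
```

## Vignette

`vignettes/gard-dose-personalization.Rmd` documents the model, the survival
machinery, the trial simulator, the synthetic-cohort calibration, and the
design decisions (rounding conventions, zero-event Weibull handling,
selection-adjusted cut-point inference, known limitations).
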