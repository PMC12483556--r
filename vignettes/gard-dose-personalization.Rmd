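---
title: "Modeling genomically adjusted radiation dose: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling genomically adjusted radiation dose: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardose)
```

## The problem

HPV-positive oropharyngeal cancer is usually cured by chemoradiation, so the
clinical frontier is not escalation but *safe de-escalation*: how much can
the radiation dose be reduced, and for whom, without losing cures? Uniform
de-escalation trials assume all patients draw the same benefit from a given
physical dose. The genomic adjusted radiation dose (GARD) framework drops
that assumption: it scores each tumor's intrinsic radiosensitivity from gene
expression and converts physical dose into a patient-specific predicted
biological effect. This package implements the full analysis chain —
signature scoring, dose algebra, survival analysis, in silico trials, and
personalized dose prescription — together with a calibrated synthetic-cohort
generator so every stage can be exercised and tested without access to
patient-level data, which remains restricted for the motivating cohorts.

## The model

**RSI.** The radiosensitivity index estimates a tumor's surviving fraction
after a single 2 Gy fraction from the within-sample ranks of ten genes
(AR, JUN, STAT1, PRKCB, RELA, ABL1, SUMO1, CDK1, HDAC1, IRF1), each
multiplied by a published coefficient (`rsi_signature()`). Ranking makes the
score invariant to any monotone normalization of expression. Whether the
original pipeline ranks within the ten signature genes or the whole array is
not fully pinned down in the literature we transcribed the coefficients
from; we default to signature-only ranking and expose `rank_scope = "all"`
for the alternative. Scores are surviving fractions, so values outside
(0, 1] are clipped with a warning rather than silently accepted.

**From RSI to GARD.** The linear-quadratic model gives cell survival
$S = \exp(-\alpha D - \beta D^2)$. Treating RSI as $S$ at a single $d = 2$
Gy fraction and fixing $\beta = 0.05\,\mathrm{Gy}^{-2}$ (a standard
simplification; patient-specific $\beta$ is a non-goal) yields the genomic
linear coefficient

$$\alpha_g = -\frac{\ln(\mathrm{RSI})}{n\,d} - \beta d, \qquad n = 1,\ d = 2\ \mathrm{Gy},$$

and, for a clinical plan of $n_c$ fractions of $d_c$ Gy,

$$\mathrm{GARD} = n_c\, d_c\,(\alpha_g + \beta d_c).$$

At 2 Gy per fraction this reduces to $-n_c \ln(\mathrm{RSI})$ exactly — an
identity the test suite enforces to machine precision, because it uniquely
pins the algebra given the stated constants. RSI values above $e^{-0.2}$
imply $\alpha_g < 0$; we keep such patients (with a warning) since GARD
stays non-negative whenever $d_c \ge 2$ Gy. EQD2 uses the standard
correction $D\,(d + \alpha/\beta)/(2 + \alpha/\beta)$ with $\alpha/\beta =
10$ Gy by default (configurable); the source analyses never state their
value, and 10 Gy reproduces the expected 69–71 Gy standard-dosing band.

**Inverse prescription.** Solving the GARD equation for dose gives the
minimum total dose at a chosen dose per fraction reaching a target GARD:
$D = \mathrm{target}/(\alpha_g + \beta d)$. Fraction counts round *up* (the
achieved GARD never undershoots the target), while whole-Gy display doses
take the integer part, which reproduces the published 31 and 113 Gy
personalized-dose extremes from the delivered-GARD extremes 71.7 and 19.7.
Rounding to nearest would print 114 for the upper bound; the integer part is
the convention that matches both printed endpoints. Patients with
$\alpha_g + \beta d \le 0$ cannot reach any positive target at that
fractionation and are reported as unreachable rather than extrapolated.

## Survival machinery

Kaplan-Meier estimation and Cox regression delegate to the `survival`
package (Efron ties, Wald intervals); both are cross-checked in the tests
against hand-coded oracles (a product-limit hand computation; a brute-force
partial-likelihood grid). The two-sample log-rank statistic, the
maximally selected cut-point scan, censored Weibull fitting, and the IPCW
time-dependent AUC are implemented in-package:

- **Log-rank / cut-point scan.** We use the standardized form
  $(O-E)/\sqrt{V}$ with the hypergeometric variance. The scan over candidate
  cuts (observed marker values, each side at least 10% of the cohort by
  default) selects the cut *maximizing* $|z|$ — i.e. minimizing the log-rank
  p-value, the standard reading of "optimal" two-group stratification; the
  literal minimal statistic would pick the worst split. Because the selected
  statistic is the maximum over many correlated tests, the naive chi-square
  p-value is anti-conservative; we report it (the motivating analysis is
  explicitly hypothesis-generating) alongside an optional permutation
  adjustment that re-runs the scan on marker permutations. The scan is
  rank-based, hence invariant to monotone marker transforms, and is computed
  by cumulative sums over the marker ordering, so a full scan costs little
  more than one log-rank test.
- **Weibull fits.** The default is censored maximum likelihood (optimized on
  log-parameters; cross-checked against `survreg`). A least-squares fit to
  the KM steps at event times is also exposed, since arm-level outcome
  summaries evaluated at discrete time points are sometimes fit that way;
  on clean Weibull data the two agree within a few percent. A group with
  zero events cannot identify a proper Weibull: the default returns an
  explicitly flagged plateau model $S(t) \equiv 1$ over the observed
  horizon, with a configurable pseudo-event fallback (one event at the last
  follow-up) when a proper distribution is required.
- **IPCW AUC.** Cumulative-case / dynamic-control AUC at a horizon, with
  censoring corrected by inverse-probability-of-censoring weights from the
  KM estimate of the censoring distribution (cases $1/\hat G(T_i^-)$,
  controls $1/\hat G(t)$, ties counted one half). With no censoring before
  the horizon every weight is 1 and the estimator equals plain pair
  counting, which the tests assert to $10^{-12}$.

## In silico trials

Virtual patients are drawn by **smoothed bootstrap**: resample the source
RSI values with replacement and add Gaussian noise with Silverman's
rule-of-thumb bandwidth (`nrd0`), i.e. sample from a kernel density estimate
of the source distribution. Noise can push values outside the unit interval;
we clip to (0.001, 0.999) and log the count, preserving the sample size.

Three designs are simulated, each with 200 patients per arm and 100
replicates by default:

1. **Unselected de-escalation** (70 Gy/35 fx vs 60 Gy/30 fx): each arm's
   GARD is computed at its schedule, patients are classified at the GARD 42
   cut (boundary in the high group), and the arm survival curve is the
   GARD-group-weighted average of the two group Weibull models. At 2 Gy per
   fraction GARD scales exactly with total dose, so de-escalation moves the
   patients with GARD between 42 and 49 (at 70 Gy) into the low group —
   which is the mechanism that makes empiric de-escalation inferior.
2. **GARD-selected de-escalation**: only patients still GARD-high at 60 Gy
   are de-escalated; everyone else stays at 70 Gy. By construction the
   experimental arm's group composition matches the control arm in
   distribution, so the design predicts equal survival — the simulator's
   replicate means agree within Monte Carlo noise.
3. **Personalized iso-GARD prescription**: every patient receives the
   minimum 2 Gy/fraction dose achieving a fixed GARD target (default 32, an
   equipoise target whose achieved subgroup matches whole-cohort survival).
   The report tabulates per-patient dose and fraction deltas against the
   delivered plan and the 35-fraction reference, flags underdosed patients,
   and summarizes the population dose savings.

Arm survival is predicted analytically (the weighted-average mixture);
replicate variability then comes from the random group composition, and
replicate 36-month OS values yield 2.5/97.5 percentile intervals. Group
Weibull models are fit once on the source cohort at delivered doses and
reused across arms and replicates — they play the role of "the original
outcomes", not of a per-replicate refit. Whether virtual-patient outcomes
should instead be sampled per patient is an open modeling choice; the
analytic mixture is the default because arm-level prediction is what the
weighted-average construction defines, and per-patient sampling would only
add binomial noise around the same means.

The `find_equipoise_threshold()` scan returns the smallest GARD value whose
achieved subgroup has horizon OS at least the whole-cohort OS. Under a
positive GARD-survival association this condition holds in expectation for
*every* threshold (the subgroup at the minimum is the whole cohort), so in
finite samples the returned value reflects where sampling noise first
favors the subgroup; we document it as a hypothesis-generating candidate,
not an estimator with sampling guarantees.

## The synthetic cohort generator

The generator emulates the statistical structure of a 191-patient
HPV-positive oropharyngeal cohort treated with definitive radiotherapy:

- **GARD distribution.** GARD at the 70 Gy/35 fx reference (not RSI) is the
  calibrated quantity, because every published summary statistic lives on
  the GARD scale; RSI follows exactly via $\mathrm{RSI} =
  \exp(-\mathrm{GARD}_{70}/35)$. The default family is a lognormal (positive
  support, two parameters, enough right tail), fit by least squares on
  relative errors to median 39.1, IQR 12.6, $P(\mathrm{GARD}\ge 42) = 0.37$
  and $P(\mathrm{GARD}\ge 49) = 0.16$ — the two exceedance targets derived
  from mean in silico group sizes of 74/200 at 70 Gy and 32/200 at 60 Gy
  (GARD at 60 Gy $\ge$ 42 is GARD at 70 Gy $\ge$ 49). The fit lands within
  about 1% of every target; gamma and zero-truncated normal alternatives are
  selectable.
- **Schedules.** A mix dominated by 70 Gy/35 fx (55%) and 69.96 Gy/33 fx
  (35%), with small fractions of 66, 60, 74 and 51 Gy plans spanning the
  reported 51–74 Gy range; this reproduces an EQD2 median of 70.0 with IQR
  about 0.7 Gy.
- **Outcomes.** The default grouped model is self-calibrating: the
  GARD-high group is anchored at $S(36) = 0.995$ and $S(60) = 0.990$ (a
  literal 100%-survival group admits no proper Weibull; the plateau option
  exists for exact replication), and the low-group Weibull is solved so the
  population mixture hits 94.1% OS at 36 months and 87.3% at 60 months
  given the calibrated high fraction. A continuous alternative plants a
  chosen log hazard ratio per GARD unit (default −0.06) on a Weibull
  baseline, for parameter-recovery testing.
- **Censoring.** Administrative at 60 months, combined with a uniform
  accrual-window potential follow-up of 21–135 months before capping —
  emulating 2008–2017 accrual with a 2019 close-out. Censoring is
  independent of outcome, so KM estimates remain unbiased.
- **Covariates.** T4, N2–3, smoking >10 pack-years and ECOG >0 flags are
  generated as independent Bernoulli draws with prevalences 0.10, 0.55,
  0.45 and 0.30 — field-plausible values chosen once; the real joint
  distribution of radiosensitivity with clinical covariates is unpublished,
  so synthetic covariates are deliberately outcome-independent and the
  multivariable analyses on synthetic data test machinery, not biology.

**What passing tests do and do not show.** The generator reproduces the
published population structure (GARD quantiles, dosing mix, survival
proportions, censoring pattern) but not real-data features such as
measurement error in expression profiling, informative censoring,
covariate-radiosensitivity correlation, or deviations from Weibull
hazards. Green tests certify the machinery and the calibration, not
clinical validity on a new cohort.

## Numerical choices and problem sizes

- Dose solver rounding: values are rounded at $10^{-9}$ before
  ceiling/floor so exact inverse round trips are not bumped to the next
  integer by floating noise.
- Calibration and Weibull optimizations use Nelder-Mead on log-scale
  parameters with tight relative tolerances; the KM curve-fit initializes
  from the linearized Weibull plot.
- The permutation adjustment uses the `(1 + \#exceed)/(B + 1)` estimator.
- Test problem sizes were chosen to keep the full suite fast while leaving
  comfortable statistical margins: recovery studies use 100 cohorts of
  n = 500; distributional checks use single cohorts of n = 2000–5000 and
  bootstrap draws of 50,000; trial direction checks use the default 100
  replicates of 200 patients per arm from a 191-patient source.

## Known limitations

- The packaged signature coefficients are transcribed from the published
  10-gene model; laboratories with their own normalization conventions
  should supply a signature file and validate the rank scope.
- Chemotherapy effect, normal-tissue toxicity beyond fraction counting, and
  competing risks are out of scope.
- The equipoise threshold scan is descriptive (see above).
- Trial predictions inherit the grouped Weibull outcome model; arms are
  exchangeable draws, with no accrual, drop-out, or protocol deviation
  structure.
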