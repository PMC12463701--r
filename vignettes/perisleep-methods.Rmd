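---
title: "Methods: claims-based phenotyping of maternal sleep disorders and perinatal outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based phenotyping of maternal sleep disorders and perinatal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisleep)
library(data.table)
```

## The problem

Administrative health-insurance claims record one ICD-coded diagnosis per
service line, with a person identifier, a family identifier, and a service
date. Nothing in the data says "this woman was pregnant from March to
December and delivered a singleton by cesarean": pregnancy episodes, their
outcomes, exposure status and covariates all have to be *reconstructed*
from code streams. `perisleep` implements that reconstruction for a
specific epidemiological design — a cross-sectional cohort of commercially
insured women with singleton pregnancies, in which clinically diagnosed
sleep disorders and breathing abnormalities (ICD-10-CM F51, G25.81, G47,
R06) are the exposure and six maternal plus three newborn outcomes are
modeled with adjusted odds ratios.

Because real claims extracts of this kind are proprietary, the package is
organised around a synthetic-claims generator that emits the same table
schemas with *known* ground truth: planted exposure prevalence, planted
conditional odds ratios, and known episode structure. Every downstream
stage is validated against that truth.

## Episode reconstruction

Pregnancy-related claims (the obstetric O chapter, Z3A weeks-of-gestation,
Z33/Z34 supervision, Z37 delivery outcome, Z38 liveborn, and the ICD-9
ranges 630–679, V22/V23/V27, 765.2x) are grouped per woman with a greedy
left-to-right scan. A new episode opens when the current claim is

* at least **120 days** after the open episode's most recent live-birth
  record,
* at least **42 days** after its most recent stillbirth or abortion
  record (the named gap rules cover live birth and stillbirth/induced
  abortion; the spontaneous-abortion gap is set to 42 days by analogy,
  configurable), or
* more than **308 days** (44 weeks, a bound on any plausible pregnancy)
  after the episode's first claim when no outcome record has been seen.

"X days after" means a date difference of at least X; all dates are
calendar days and intervals are closed. Same-day duplicates on
(woman, date, code) are removed before grouping. The scan is implemented
as a small C++ kernel; the test suite checks it against an exhaustive
partitioner that enumerates every gap-consistent contiguous partition of
random claim sequences (up to 12 claims) and selects the greedy-earliest
one.

Outcome classification uses code evidence (live birth: O80/O82/Z37.0;
stillbirth: Z37.1/P95; spontaneous abortion: O03; induced abortion: O04),
with precedence live birth > stillbirth > spontaneous > induced when
families co-occur. The delivery date is the earliest claim of the winning
family (the last claim date when no outcome record exists); gestational
age is the maximum week observed across Z3A.xx / 765.2x codes, defaulting
by outcome class (39 / 30 / 10 weeks, flagged imputed) when absent; the
LMP is the delivery date minus seven days per gestational week. The
ICD-9 765.2x subcodes map to the midpoint of their documented ranges,
rounded up (765.28, "35–36 completed weeks", yields 36).

## Cohort construction

Eligibility is evaluated per episode: culmination inside
2016-01-01–2020-06-30, maternal age 18–45 at delivery (delivery year minus
birth year — year arithmetic only, matching how enrollment files record
age), not an induced abortion, no O30/O31 multiple-gestation claims
(applied to unknown-outcome episodes too), and continuous enrollment
covering every day of culmination ± 365 days (1-day administrative gaps
are *not* forgiven; stricter is safer, and the window is configurable).
One index episode per woman is chosen by the hierarchy live birth >
stillbirth > spontaneous abortion > unknown, with earliest delivery date
breaking ties (the tie-break is a package decision; the emulated design
states none).

Mother–infant dyads link a live-birth index episode to an infant sharing
the family identifier whose first claim falls within ±60 days of delivery,
nearest date winning — the temporal rule is likewise a package decision on
top of the stated family-ID matching. The maternal-outcome cohort drops
unknown-outcome index episodes; the birth-outcome cohort further drops
stillbirths and unlinked live births. The cascade report attributes every
excluded woman to the first criterion that removed her, so the flow chart
always reconciles; `emit_flowchart()` hard-fails otherwise.

## Phenotyping

**Exposure.** A woman is exposed if any claim in her ascertainment window
carries a qualifying code: any F51.*, G47.* or R06.*, and G25.81 only
within G25. ICD-9 claims (the 2015 portion of the stream) are converted
first through a shipped, editable conversion table. Each distinct ICD-10
code counts once regardless of claim multiplicity — the
one-diagnosis-per-person rule — and the burden is categorized 0 / 1 / 2+.
The window is per-woman, culmination ± 365 days: the enrollment design
guarantees complete data exactly there. Whether "R06 codes" should be
restricted to a subset of breathing abnormalities is genuinely open; the
shipped table includes all of R06.* and is user-editable.

**Maternal outcomes.** Six binary outcomes with windows anchored on the
estimated pregnancy dates: cesarean, gestational diabetes and gestational
hypertension within [LMP, delivery]; preeclampsia through delivery + 42
days (postpartum preeclampsia); postpartum depression within the half-open
interval (delivery, delivery + 365 days] — a delivery-day F53.0 is
in-pregnancy depression, not PPD. Stillbirth comes from the episode
outcome (Z37.1/P95). Cesarean evidence on a linked infant's record
(Z38.01) propagates to the mother through the dyad.

**Birth outcomes.** Three 3-level axes from infant codes: size for
gestational age (P05.1x SGA / P08.0 LGA), birthweight (P07.0x–P07.1x LBW /
P08.1 HBW), gestation period (P07.3x preterm / P08.21 post-term). Absence
of axis codes yields the reference level (AGA / normal / term); a
conflicting pair on one axis forces that axis to missing, never a silent
choice.

**Covariates.** Age groups 18–25 / 26–34 / 35–45; gestational-age groups
≤36 / 37–40 / 41–42 weeks; state of residence mapped to the nine US census
divisions; and four insurance attributes (ASO funding, CDHP type, health
exchange, product type) passed through as socioeconomic proxies.

## Models

Descriptive output uses pooled-variance t-tests and Pearson chi-squared
tests (no continuity correction; zero expected cells are rejected rather
than corrected), with percentages printed to two decimals, halves rounded
up. Period prevalence is the count of unique diagnosed women over the
eligible total.

The adjusted models are authored in the package because the estimator is
its analytical core:

* **Binary logistic regression** by iteratively reweighted least squares.
  Convergence when the maximum absolute score drops below 1e-8 or the
  relative log-likelihood change below 1e-10, within 100 iterations.
  Wald 95% CIs come from the observed-information covariance. Any
  coefficient with |β| > 15 is flagged as separated and the fit marked
  non-converged; no Haldane or Firth-type correction is applied by
  default.
* **Baseline-category multinomial logistic regression** by full
  Newton–Raphson on the stacked (K−1)·p coefficient vector with the exact
  block Hessian, under the same convergence contract. One model per birth
  axis (matching the three separate panels the design implies), reference
  levels AGA / normal / term. With K = 2 the fit reproduces the binary
  fitter to 1e-6, and category probabilities sum to one to 1e-10 — both
  are tested.

Adjustment sets: maternal models use exposure plus age group, race and
ethnicity, census division, and the four insurance attributes; birth
models add infant sex and the pregnancy complications (gestational
diabetes, gestational hypertension, preeclampsia, cesarean). Reference
levels default to age 26–34, White, South Atlantic, POS, "no"/"none", and
female infants — the reference choices are package decisions, all
configurable. Estimation is complete-case; `n_used` is always reported.
Exposure is modeled dichotomously or as burden indicators (one, two-plus;
zero as reference) for the dose-response analysis. No multiple-testing
adjustment is applied, matching the design being emulated.

## The synthetic generator

`sim_config()` defaults are a recognizable miniature of the study
conditions: exposure prevalence 3.41% with an 84.45 / 15.55 one-vs-multiple
split (and the 2…8-diagnosis tail in the reference proportions); unexposed
outcome rates of 9.93% (cesarean), 9.64% (gestational diabetes), 10.64%
(gestational hypertension), 7.16% (preeclampsia), 2.34% (postpartum
depression) and 0.51% (stillbirth); planted exposure log-odds equal to the
log of the adjusted odds ratios 1.44, 1.61, 1.60, 1.70, 3.37, 2.14 for the
maternal outcomes and 1.40/1.33 (SGA/LGA), 1.42/1.25 (LBW/HBW), 1.51/0.87
(preterm/post-term) for the birth axes; covariate margins taken from the
demographic table being emulated (age, race with 16.5% missing, division,
insurance attributes); 17.7% of live births unlinked to an infant. Dates
live on a day grid. Each woman consumes a fixed 64-draw block of a single
seeded uniform stream, so her data are byte-stable when `n_women` changes;
exposure code sets are drawn by weighted sampling without replacement from
a 15-code pool whose weights reproduce the reference family mix, and
claims dated before 2015-10-01 are emitted in ICD-9 form through the same
conversion table the pipeline inverts.

Deliberate simplifications, and what they imply for the tests:

* Outcome indicators are drawn conditionally independent of the episode
  outcome class given covariates (so a pregnancy-loss episode can carry a
  cesarean code, emitted as O75.82 so it never counts as live-birth
  evidence). This keeps the fitted models correctly specified on the
  maternal cohort; real data couple outcomes and episode classes.
* Covariate effects are modest (|log OR| ≤ 0.3) and shared across
  outcomes, so planted exposure effects dominate.
* Maternal age is drawn at the first episode; for multi-episode women the
  pipeline's age-at-index can differ by a few years. The resulting
  age-group misclassification (~3% of women) is independent of exposure
  and leaves planted-effect recovery unbiased (verified by replicate
  pilots).
* Exposure claims are dated uniformly over culmination ± 365 days, i.e.
  exactly the ascertainment window, so planted prevalence is the measured
  prevalence. Dating them relative to the LMP instead would push about a
  quarter of single-diagnosis women's claims outside the window and bias
  every planted effect toward the null — a property of real data (left
  truncation of pre-pregnancy diagnoses) that the generator deliberately
  does not emulate.
* No billing adjudication, procedure claims, or geographic realism beyond
  one representative state per census division (the division is a pure
  function of state, so this loses nothing for the models).

Passing tests therefore demonstrate that the pipeline's logic is exact and
its estimator well-calibrated under the stated generative model — not that
the code is robust to miscoded, truncated or adversarial real-world
claims beyond the pathology classes that `inject_pathologies()` covers
(enrollment gaps, twin codes, conflicting birth-outcome codes, duplicate
claims, extra episodes).

## Problem sizes and numerical choices

The test suite validates grouping against the exhaustive oracle on 10,000
random sequences of up to 12 claims, and checks Wald CI coverage of all
twelve planted effects over 200 pipeline replicates at n = 20,000 women —
the scale at which the rarest outcome (stillbirth, 0.51%) still yields a
stable adjusted fit. Coverage is asserted within a three-sigma binomial
band around the nominal 95% (≥ 0.90 per effect, ≥ 0.93 for gestational
hypertension), bounds fixed from binomial reasoning before the experiment
was run. The acceptance script reports adjusted-OR estimates as geometric
means over five replicates at the same n. Degenerate inputs are rejected
loudly: rank-deficient designs name the collinear columns, zero cells
reject the odds-ratio and chi-squared computations, infeasible simulation
configurations (episodes that cannot fit the culmination window) fail at
construction.

## Known limitations

* The episode builder implements only the in-scope subset of a full
  multistage pregnancy-identification algorithm: diagnosis codes only (no
  procedure codes), a fixed pregnancy-related code list, and explicit
  stand-in defaults where the full algorithm's internals are not public
  (maximum span, GA defaults, overlap precedence).
* Wald intervals are first-order; for outcomes with a handful of events in
  the exposed group (stillbirth, LGA at small n) their coverage is
  approximate, which is why the acceptance band is binomial rather than a
  point value.
* Complete-case adjustment discards women with missing race or division
  (~17% under the default margins), mirroring the emulated design rather
  than imputing.
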