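---
title: "Measuring consultation complexity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring consultation complexity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcomplexity)
```

## 1. What the package measures

A *complex* general-practice consultation is one that is more difficult,
multi-faceted, or time-consuming than average. The package operationalises
this as a binary per-consultation classification: a consultation is
complex when at least one *retained complexity factor* is present. Factors
come in two kinds:

* **Consultation factors** describe the content of a single consultation —
  a mental-health topic coded within it, two or more diagnoses drawn from
  distinct code chapters, three or more unique substances prescribed, and
  so on. They are detected from the events and prescriptions linked to
  that consultation only.
* **Patient factors** describe enduring characteristics — dementia ever
  recorded, domestic violence in the prior year, ≥3 major long-term
  conditions. They are detected from the patient's whole coded history
  through a lookback window anchored at each consultation date.

The measure is deliberately binary. The factor coefficients estimated
during validation are associations with duration, not weights; combining
them into a cumulative severity score is out of scope by design.

## 2. The Delphi engine

Candidate factors are selected by a two-round expert panel. Each panelist
scores each factor on a 1–5 scale; scores 3–5 count as endorsement, score
1 as rejection, score 2 as neither (it still enters the denominator).
Classification per round uses four strict inequalities:

* **endorsed**: endorsement proportion > 0.70 *and* rejection proportion < 0.20;
* **rejected**: endorsement proportion < 0.40 *and* rejection proportion > 0.20;
* **uncertain** otherwise.

Strictness follows the literal threshold wording: a factor endorsed by
exactly 70% of voters is *uncertain*, and a factor rejected by exactly 20%
can be neither accepted nor rejected on that criterion. Both boundary
cases are exercised in the test suite. Users who prefer inclusive
comparisons can shift the thresholds infinitesimally via
`delphi_thresholds()`.

Round-1 endorsed/rejected statuses are final. Uncertain factors, plus
factors newly suggested by panelists, are voted on in round 2 under the
same rules; whatever is still uncertain afterwards is rejected. Between
rounds each panelist receives a feedback report (`feedback_report()`)
placing their own score against the panel median and interquartile range.

Conventions where the procedure is silent:

* **Abstentions** (missing scores) are excluded from the denominator; the
  output metadata notes this choice.
* **Median of an even panel** is the mean of the two central scores, so
  medians such as 3.5 occur; the IQR uses the inclusive (type-7) quartile
  convention.
* **Reworded items between rounds** keep their identity via `factor_id`;
  wording is metadata.

The package ships the complete two-round bookkeeping of the measure's
development panel (`delphi_history()`): 45 candidate indicators, of which
34 were endorsed (17 consultation, 17 patient). The acceptance suite
replays this history through `run_two_rounds()` using constructed vote
blocks that realise each recorded status, and checks every final status.

## 3. Code sets and window semantics

Factors are defined against flat code lists (`load_codesets()`), one row
per (factor, code). Matching is **exact-string** on the code field — no
hierarchy expansion — because deposited code sets are flat lists. The
*chapter* of a code is its first character (the Read v2 convention),
case-sensitively; a chapter map can override this for other terminologies.
The bundled code sets are toy stand-ins written in a Read-like style; they
are synthetic and make no claim to reproduce any deposited clinical code
set.

Lookback windows are encoded in days (previous year = 365, 2 years = 730,
3 years = 1095, 3 months = 91, 2 months = 61) or `ever`. The window is
**half-open**: an event activates a patient factor at consultation date
`d` when its date `e` satisfies `d − L < e ≤ d`. Hence an event exactly
`L` days before the consultation is *outside* the window, an event on the
consultation date is *inside*, and nothing after `d` is ever visible (no
lookahead). Where wording for the polypharmacy window differed between
the panel phrasing ("last 2 months") and the modelling phrasing
("previous 3 months"), the modelling phrasing (91 days) is used.

Count rules:

* *≥2 diagnoses from unique chapters*: distinct chapters among the
  consultation's diagnosis codes (the bundled set restricts this to an
  explicit diagnosis-code list; whether administrative chapters should
  count is genuinely open, so the code list is the control).
* *≥3 unique substances prescribed*: distinct `substance_id`s issued at
  the consultation. Substances are counted as provided; no attempt is made
  to split combination products.
* *Frequent attender*: ≥14 face-to-face consultations in the prior-year
  window, **excluding the index consultation** — a patient's first-ever
  consultation can never be "frequent" by itself. The threshold 14 is the
  95th centile of prior-year counts in the development cohort and can be
  respecified from data (`specify_percentile_threshold()`).
* *Polypharmacy*: ≥9 unique substances prescribed in the prior 91 days.
* *First consultation after a diagnosis*: the chronologically first
  consultation dated on or after the diagnosis code with no intervening
  consultation; same-day counts, and same-day ties break by
  `consultation_id`.

## 4. The development pipeline

1. **Prevalence screen** (`prevalence_screen()`): factors applying to
   strictly fewer than 0.05% of consultations (consultation factors) or
   patients (patient factors) are excluded. The comparison is strict, so a
   factor at exactly 0.05% survives. A patient counts once if the factor
   holds at any of their consultations in the window.
2. **Percentile respecification** (`specify_percentile_threshold()`):
   qualitative "high count" factors become integer thresholds at the
   empirical 95th centile. The quantile is the inverse-ECDF (type-1)
   quantile, rounded up to an integer — the smallest observed value at or
   above the centile. On a constant sample this returns the constant; on
   `1:100` at 0.95 it returns 95.
3. **Reclassification** (`reclassify_low_prevalence()`): consultation
   factors too rare at consultation level can be moved to patient level
   with a window, merging codes into an existing patient factor when one
   exists (a window conflict is an error). In the shipped bookkeeping four
   factors move this way (palliative care, homelessness, domestic
   violence, safeguarding), leaving 11 consultation factors to enter the
   initial model.
4. **Mixed-effects validation** (`fit_duration_model()`): duration in
   minutes on binary factor indicators with random intercepts for practice
   and patient, REML estimation via `lme4::lmer`. Patients belong to one
   practice, so the patient effect is nested within practice; globally
   unique patient ids make the crossed formula equivalent, and that is
   what is fitted. Consultation-factor and patient-factor models are
   always fitted separately, never jointly. Inference is Wald-style:
   normal 95% intervals and two-sided p-values from estimate/SE. (The
   development cohort had ~7×10⁵ consultations, where Wald, profile and
   degree-of-freedom-corrected intervals coincide to printed precision;
   at small simulated n the Wald choice is slightly anti-conservative,
   which the coverage test tolerates explicitly.) Univariable mode refits
   the model one factor at a time and is reported for context only — it
   plays no role in selection.
5. **Elimination** (`backward_stepwise()`): a single initial pass removes
   every factor whose multivariable coefficient is negative (shorter
   consultations cannot evidence complexity under the duration-validation
   logic); the sign pass is not re-checked on later refits. Then one
   factor is removed per refit — the largest p at or above 0.05 — until
   all survivors are significant. The removal log records each step.
   `prune_terms()` applies the same policy to a fixed coefficient table
   without refitting, which is how the shipped development-cohort
   bookkeeping is replayed: 11 → 10 consultation factors (first
   consultation after cancer, p = 0.118) and 15 → 7 patient factors (four
   sign exclusions, then frequent attender, severe mental illness,
   learning disability and polypharmacy by p-value).
6. **Assembly** (`assemble_measure()`): the union of the two surviving
   sets, with an explicit override list for factors force-retained on
   grounds outside the elimination (the shipped bookkeeping records five
   such factors retained despite non-significance in a later revalidation
   cohort); overrides are recorded in the result's attributes.

## 5. The synthetic generator as a stated world

`simulate_dataset()` emulates the *structure* of a CPRD-style extract: an
age–sex stratified panel of patients across practices, face-to-face
consultations with durations, coded events inside consultations, history
events at lookback offsets, and prescriptions. Durations follow exactly
the mixed-model equation of Section 4, truncated below at 1.0 minute
(consultation durations are positive; the floor affects ~0.3% of draws at
the default SDs and shifts the mean by ~0.003 minutes, negligible against
all tolerances used).

Defaults define the stated world and are not tuned to test outcomes:

* **Effects**: the development cohort's final-model coefficients —
  baseline 9.78 minutes and the retained factor effects (mental health
  +3.85, emergency admission +7.76, …) via `default_factor_effects()`.
* **Variance components**: SDs 0.5 (practice), 1.0 (patient), 3.0
  (residual) minutes. The residual SD is chosen so that the total SD
  (~3.2) gives a coefficient of variation of ~⅓ around a 10-minute mean,
  a realistic scale for surgery consultations; practice heterogeneity is
  kept smaller than patient heterogeneity.
* **Prevalences** (`default_factor_prevalence()`): plausible per-
  consultation/per-patient rates chosen once (mental-health topic 10%,
  ≥3 substances 20%, ≥2 chapters 15%, emergency admission 0.2%, rare
  factors down to 0.02% to exercise the 0.05% screen). The published
  prevalence tables were not available in the main text, so these are the
  package's own stated world and are documented here precisely so that a
  green test is read as "the pipeline recovers *this* world", not as a
  reproduction of any cohort. The acceptance simulation raises the
  emergency-admission prevalence to 1% to stabilise that estimate, as its
  target prescribes.
* **Panel and activity**: 10-year age bands with plausible weights (no
  claim to any registry's distribution — supply your own), Poisson
  consultation counts at a configurable rate, uniform dates in the study
  window, all patients registered throughout.

Planting: consultation factors are planted per consultation with their
configured probability (codes for code-match rules, the threshold number
of distinct codes/chapters/substances for count rules, a same-day
diagnosis for first-consultation rules). Patient factors assign carrier
status per patient and plant one history event at a uniform random offset
inside the factor's lookback window before the patient's *first*
consultation — the measure tests window membership, not event
multiplicity, so one event suffices; for finite windows, later
consultations may legitimately fall outside the window again. Factors
derived from the consultation table itself (frequent attender) cannot be
planted; their prevalence emerges from the consultation process.
Background administrative codes (chapter `Z`, matching no code set) are
added as noise.

Because planted codes are real codes, plantings can interact — a
consultation mental-health code also activates the patient-level
drug/alcohol history window for later consultations when codes are
shared. The generator therefore derives its **truth flags by recounting
the realized tables**, with `recount_flags()`: a deliberately plain,
loop-based implementation kept independent of the vectorised
`compute_flags()`. The duration model uses these realized flags, and the
test suite asserts bit-for-bit agreement between the two implementations
as well as against hand-computed micro-fixtures.

All randomness flows from one seeded stream with a fixed draw order
(practice intercepts, panel, patient intercepts, consultation counts and
dates, consultation-factor planting in registry order, patient-factor
planting, background codes, residuals), so identical configurations give
identical datasets; the caller's RNG state is restored.

What the generator does **not** emulate: seasonal or weekday structure,
registration churn, consultation-count/duration dependence within
patients (relevant to the known shorter-but-more-frequent pattern for
dementia and housebound patients, which is out of scope), correlated
factor prevalences beyond code sharing, coding noise (missed or
miscoded events), or duration digit preference. A green parameter-recovery
test therefore establishes that the pipeline is a consistent estimator of
its own generative model at realistic scale — not that it reproduces any
real cohort's coefficients.

`simulate_votes()` is the Delphi counterpart: `clear_endorse` and
`clear_reject` factors use deterministic score compositions that guarantee
the corresponding classification at any panel size, while `borderline`
factors draw i.i.d. scores with endorsement probability 0.70 and rejection
probability 0.15 — sitting exactly on the acceptance thresholds so that
classification frequencies can be checked against exact multinomial
enumeration.

## 6. Numerical and degenerate-input choices

* Strict inequalities at all four Delphi thresholds; ties fall to
  uncertain/not-rejected.
* Half-open lookback windows; exact-day arithmetic on `Date`s.
* Age at consultation = consultation year − birth year (records carry
  birth year only); default reporting bands 0–4, 5–14, …, 75–84, 85+.
* The difference in mean duration between complex and non-complex
  consultations uses a Welch-style large-n normal interval; with either
  group empty the summary is still produced with the difference and CI
  `NA`.
* Zero random-effect variances are legal: `lmer` reports a singular fit
  and the estimates equal OLS, which the suite checks against an `lm`
  oracle.
* A factor constant across all consultations is a singular design and a
  hard error naming the factor; non-convergence messages are captured on
  the fit object (`$messages`, `$converged`) rather than swallowed.
* Stepwise with everything eliminated returns the intercept-only model
  with a warning.
* An optional duration cap exists but defaults to off: whether source
  durations were cleaned before modelling is unknown, so the generator
  does not guess.

## 7. Known limitations

* Only coded data are visible: factors that create real complexity but go
  uncoded (classically, medically unexplained symptoms) are invisible to
  the measure, and the toy code sets are illustrative only.
* The REML-vs-ML choice for stepwise p-values, and one-at-a-time removal
  with refitting, are the conservative standard but are choices; both are
  switchable/logged rather than asserted as the only reading.
* Wald inference is slightly anti-conservative at small cluster counts;
  with ≥50 practices (the scale used in acceptance runs) the effect is
  immaterial.
* The bundled age–sex weights and factor prevalences are stated-world
  defaults, not estimates; analyses of real data should supply their own
  code sets and leave the generator to testing.
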