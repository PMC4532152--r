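---
title: "Top-down COPD cost accounting and smoking-standardised projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Top-down COPD cost accounting and smoking-standardised projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdcosts)
library(data.table)
```

## The method and its assumptions

`copdcosts` implements a register-based *top-down* cost-of-illness
design for COPD. Rather than identifying a patient cohort and summing
its costs bottom-up, the method selects, from national registers of
services and benefits, exactly those events whose recorded primary
cause is COPD, and prices them with national unit costs. The key
assumptions are:

* **Attribution by primary diagnosis.** An event counts if and only
  if its primary ICD-10 code starts with `J43` (emphysema) or `J44`
  (COPD); subcodes (`J44.0`, ...) qualify by prefix. Episodes where
  COPD is a secondary diagnosis are excluded, which makes the estimate
  conservative (some exacerbations are coded as pneumonia or acute
  bronchitis), while avoiding the overestimation of counting every
  episode of a multimorbid COPD patient.
* **Medication by entitlement + anticholinergic use.** Pharmacy
  registers carry no diagnoses. COPD drugs are defined person-level:
  purchases of respiratory drugs by persons entitled to special
  reimbursement for obstructive pulmonary disease *and* using inhaled
  anticholinergics. Both flags are properties of the person, so every
  purchase of a qualifying person qualifies.
* **Indirect costs as lost man-years.** Sickness-allowance days and
  disability-pension person-years are converted into lost man-years
  and valued at a per-man-year unit cost. Mortality-related losses and
  presenteeism are excluded.

The projection assumes that *smoking history, age and sex determine
COPD-related costs*: base-year costs per stratum, divided by the
stratum's weighted count of active smokers and recent quitters, stay
constant per "smoker-equivalent"; only the number of equivalents
(smoking trends × population projection) and the price level change.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| unit costs (PHC day, SHC day, visit, man-year) | 142 / 590 / 200 / 24,600 | EUR, 2006 | published national 2006 unit costs; other years by price index |
| `days_per_man_year` | 260 | working days | a 5-day working year; published allowance figures imply ≈260.6 but no source states the divisor — kept configurable |
| smoking weights | 1 / 1 / 0.75 / 0.5 | — | the standard recency weighting of active smokers and 1–3 / 3–5 / 5–10-year quitters |
| `retirement_age` | 65 | years | strata at/above it contribute no indirect cost: already retired, morbidity causes no productivity loss |
| `inflation` | 0.02 | fraction/yr | the conventional long-run assumption for nominal projections |
| `copd_diagnosis_share` | 0.8 | probability | synthetic worlds only: share of generated events carrying a true COPD code |

## What the synthetic generator emulates — and what it does not

`generate_registers()` emits person-level event rows with the schema
of national care/medication/allowance/pension register extracts. Per
stratum-year and category, event counts are **Poisson** with mean
`rate × age_multiplier × weighted smoker-equivalents`. The Poisson
choice is a design decision, not an empirical claim: the accounting
method is deterministic given the registers, and a known counting law
gives replication-based tests exact error bars (mean within 3 standard
errors over ≥100 seeds). Diagnosis codes mix true COPD rubrics
(including subcodes, to exercise prefix matching) with a configurable
distractor list (`J18`, `J45`, `I50`), so the filters have something
to reject. Drug purchases carry gamma-distributed EUR amounts and
person-level entitlement/anticholinergic flags drawn once per person.

The generator does **not** emulate: overdispersion or epidemic-year
clustering of admissions, within-person correlation of care and
benefit events, coding drift over calendar time, or any causal link
between the smoking fractions and event rates beyond the equivalents
denominator. A green end-to-end test therefore establishes that the
*accounting and projection arithmetic* is correct on registers with
the assumed structure — not that the synthetic world is demographically
realistic. Default rates in `default_sim_config()` were chosen once so
national totals land at the order of magnitude of published COPD
register studies (tens of thousands of hospital days per year, roughly
two thousand disability pensions); they are free parameters, stated in
one place and never tuned against test outcomes.

## Numerical choices

* **Rounding.** All intermediate arithmetic is exact floating point.
  Rounding (half-up, via `round_half_up()`; base R's half-to-even does
  not reproduce published tables) happens exactly twice: to integer
  Euros when `assemble_breakdown()` builds the reporting table, and in
  `per_capita()` / `percent_change()`. Totals are sums of *rounded*
  components, so additivity holds exactly in the integer-Euro
  representation — the same convention published cost tables follow.
* **Price index.** Missing index years are a hard lookup error, never
  interpolated: silent interpolation hides data problems.
* **Smoking extrapolation.** "Fractions keep changing at their
  historical rate" is read as *linear in percentage points* (OLS slope
  over the history window), the simplest reading; a log-linear
  (`method = "proportional"`) mode is provided for sensitivity
  analysis. Predictions are clamped to [0, 1]; if the four category
  fractions sum above 1, the excess is truncated from the largest
  category, deterministically (ties broken in category order).
* **Degenerate strata.** A stratum with positive base-year cost but
  zero smoker-equivalents makes the standardisation undefined and is a
  hard error naming the stratum; zero cost with zero equivalents
  standardises to 0.

## Design decisions made where the design was open

* **Direct and indirect channels are standardised and projected
  separately per stratum.** The single published mechanism speaks of
  "costs"; separating the channels is necessary to report the
  direct/indirect split of projected years and to apply the
  retirement-age gate to the indirect channel only.
* **Known gap between printed hospital costs and days × unit cost.**
  Published hospitalisation cost cells also include DRG-priced medical
  procedures, whose aggregate rides the hospital channel. Pricing
  *days only* is therefore a lower bound on those cells (about 0.1 %
  low for secondary care in 2006, 0.35 % for primary care); the
  fixture tests assert the bound rather than pretending exact
  reproduction is possible from day counts.
* **Pension person-years may be fractional.** Published pension costs
  differ from `subjects × 24,600` by ~0.03 %, implying fractional
  person-years behind the printed subject counts; the pipeline
  supports fractional quantities and never forces the product to
  match.
* **J33 guard.** Registry extracts occasionally carry `J33` (nasal
  polyp) as an allowance/pension cause — almost certainly a typo for
  `J43`. The filter rejects it but emits a warning with the count, so
  the miscoding is auditable rather than silently guessed at.
* **Historical medication costs are pass-through.** Drug purchase
  amounts come from the medicines statistics already in current Euros;
  no second inflation adjustment is applied to them.
* **Inflation applies to both channels.** The projection inflates
  direct and indirect nominal series alike (the real series is kept
  alongside, and the nominal/real ratio factorises exactly as
  `(1+inflation)^(year-base)`, which the tests assert).
* **Population projection fallback.** When no projection file is
  supplied, the pipeline extrapolates each stratum's population
  linearly (OLS, clamped at 0) — crude, but transparent and stated.

## A compact run

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = default_sim_config(seed = 42, years = 2002:2006),
                       base_year = 2006, projection_years = 2007:2030,
                       seed = 42)
bundle <- run_pipeline(cfg)
bundle$breakdown       # historical integer-Euro table
bundle$projection      # real and nominal projected series
bundle$summary         # endpoints and percent change
```

## Known limitations

The projection is a point estimate: no uncertainty intervals are
produced, matching the method's published use. Reproducing any
specific national headline figure (e.g. a 2030 total) requires the
actual stratum-level tobacco statistics and official population
projection, which are not shipped here; the tests therefore verify the
projection *mechanism* (stationarity identity, inflation
factorisation, slope recovery, brute-force oracle equality) rather
than any headline number. Historical accounting accuracy is bounded by
register coding practice — primary-diagnosis attribution is
conservative by construction.
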