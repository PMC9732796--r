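---
title: "A Markov cost-utility model for diabetic foot ulcer recurrence prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model for diabetic foot ulcer recurrence prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfuheor)
```

## The problem

People whose diabetic foot ulcer (DFU) has recently healed face a high risk
of recurrence, and recurrences drive most of the cost and disability of
diabetic foot disease: a severe recurrent ulcer (SINBAD score of 3 or more)
costs the health system several times as much per month as remaining
ulcer-free, and may progress to amputation. Digital self-management tools aim
to reduce recurrence, but at the time such tools reach the market there is
typically no comparative effectiveness evidence. The question a payer then
asks is not "what is the ICER?" but the inverse: **how much recurrence
reduction would the tool need to deliver to be worth paying for?**

`dfuheor` answers that question with a Markov cohort cost-utility model and a
threshold analysis, and additionally provides the descriptive statistics used
to characterise small feasibility cohorts in this disease area (SINBAD
severity scoring, baseline summaries, and a restricted-mean ulcer-free-time
estimator).

## The model

### States and transitions

The cohort model has six health states. Everyone enters in `post_dfu`
(healed ulcer, at risk of recurrence), at a baseline age of 67 years with a
70% male cohort; cycles are one month long.

| state             | meaning                                   | utility | monthly cost (GBP) |
|-------------------|-------------------------------------------|---------|--------------------|
| `post_dfu`        | healed ulcer, at risk                     | 0.64    | 180.70             |
| `nonsevere_dfu`   | active ulcer, SINBAD < 3                  | 0.61    | 453.83             |
| `severe_dfu`      | active ulcer, SINBAD >= 3                 | 0.47    | 972.30             |
| `amputation`      | amputation procedure + perioperative care | 0.34    | 1106.19            |
| `post_amputation` | long-term care after amputation           | 0.47    | 311.96             |
| `death`           | absorbing                                 | 0       | 0                  |

Allowed monthly moves: from `post_dfu` to a non-severe or severe ulcer or to
death (non-DFU causes); from `nonsevere_dfu` back to `post_dfu`, onward to
`severe_dfu` or to `amputation`; from `severe_dfu` back to `post_dfu`, to
`amputation` or to `death`; from `post_amputation` to `death`. Every state's
unassigned probability mass self-loops, with one exception: `amputation` is a
**one-cycle tunnel** that empties into `post_amputation` with probability 1.
The printed model structure names no perioperative mortality, so
`amputation -> death` is only available behind an explicit
`allow_perioperative_death` switch that warns when used. Direct death from
`nonsevere_dfu` is likewise structurally excluded; users convinced their
sources require it should model that mortality through the severe state or
the post-ulcer state.

### Transition probability values

The published evaluation drew its transition and mortality probabilities from
audit data and cited literature without printing them, so **the package
cannot ship the study's inputs**. `placeholder_transitions()` provides a
clearly-labelled placeholder set with plausible orders of magnitude (monthly
recurrence 0.02, split 70/30 non-severe/severe; monthly non-DFU mortality
0.003 at age 67+; healing rates 0.25 and 0.12 per month from the non-severe
and severe states). It exists so examples, demos and tests run; every
substantive analysis must supply a parameter file via `load_parameters()`,
which refuses to run with an empty `transitions` section rather than silently
using the placeholder.

### Intervention effect and compliance

The intervention (a self-management app used alongside standard care) is
modelled as a relative risk `rr` on both recurrence transitions
(`post_dfu -> nonsevere_dfu` and `post_dfu -> severe_dfu`), attenuated by
compliance:

$$ rr_{\mathrm{eff}} = c \cdot rr + (1 - c), $$

i.e. the compliant fraction `c` (default 0.90) experiences the full effect
and the rest experience standard-of-care risk. This is the simplest reading
of a single scalar compliance; it is applied to both recurrence transitions
equally, and the freed probability mass returns to the post-DFU
self-transition.

### Outcomes, discounting and corrections

Per cycle, QALYs accrue as occupancy-weighted utility times 1/12 year and
costs as occupancy-weighted monthly state costs; the app price (default
4.99 GBP/month, the monthly pricing scenario; 4.17 under annual pricing;
0 when free) is charged to the **surviving** fraction of the intervention
arm — the model does not bill the dead, and the published text does not say
otherwise. Both streams are discounted at an annual 3.5% (separately
configurable for costs and outcomes, since the outcome rate is itself a
sensitivity-analysis parameter) with the per-cycle convention
$(1+r)^{-c/12}$; a conventional annual-step mode is available for
comparison. Half-cycle correction (averaging start- and end-of-cycle
occupancy) is on by default, as is standard for Markov cohort models;
without it the end-of-cycle row is used, which is also the convention the
closed-form identities in the tests are written against.

The horizon is lifetime: cycles run until age 100 (396 cycles from age 67)
or until the surviving fraction drops below `1e-6`. Mortality is
state-constant per cycle rather than age-varying, matching a model whose
mortality inputs are aligned to health states rather than life tables; this
understates late-life mortality and is listed under limitations.

### Threshold analysis

With no effectiveness data, the key output is the threshold relative risk
$rr^*$ at which the ICER of app-plus-care versus care alone equals a
willingness-to-pay of 20,000 GBP/QALY. Because the net monetary benefit at
the target is monotone in `rr` (a stronger effect only helps), `rr*` is found
by bisection on NMB over (0, 1], iterated until the recomputed ICER is within
a relative `1e-6` of the target (at most 200 iterations; the NMB residual
divided by the target times the QALY gain bounds the relative ICER error, so
convergence is checked directly on the quantity of interest). Boundary cases
are explicit: a free effective app dominates (`dominant_at_rr1`), and with
zero compliance no threshold exists (`no_threshold`), reported with NMB
diagnostics rather than an arbitrary number. Results are reported both as
`rr` and as the relative reduction $1 - rr$ in percent, the form decision
makers quote.

### One-way sensitivity analysis

`owsa()` recomputes the NMB with each parameter at its low and high value,
all others held at base, each endpoint a full independent model evaluation
(no caching), and returns bars sorted by descending width — tornado order —
with alphabetical tie-breaking so the output is deterministic and invariant
to input order. No published ranges exist for this model, so the defaults are
the conventional deterministic-sensitivity choices: ±20% for probabilities,
utilities, costs, price and compliance (clipped to their domains), and an
absolute 1.5%–6% band for the two discount rates. On the placeholder set the
widest bars are the outcome discount rate, post-ulcer mortality and the
severe-recurrence probability — the qualitative ranking reported for the
original model — but since that ranking depends on unprinted inputs it is a
demonstration, not an asserted test.

## Feasibility-cohort statistics

`dfu_cohort()` ships the 15-patient feasibility cohort (transcribed
per-patient baseline table). `summarize_cohort()` reproduces its printed
summaries exactly: mean (SD) age 60.8 (9.3) years, BMI 32.94 (6.13), SINBAD
2.1 (1.0), 3/15 women, 12/15 type 2 diabetes, 9/15 previous smokers, 2/15
completers, 6/15 reulcerations. SD uses the sample (n−1) convention, which is
what reproduces every printed value.

`ulcer_free_time_summary()` estimates mean time from healing to recurrence as
the Kaplan–Meier restricted mean (restricted to the largest observed time, so
administrative censoring at 52 weeks is handled), with a nonparametric
bootstrap percentile 95% CI. The bootstrap was chosen because the reported
interval for this quantity (74.0–484.0 days around 273.0) is markedly
asymmetric, which a normal-approximation interval cannot produce; the
per-patient recurrence times behind that number are not public, so the
estimator is validated on synthetic data and against a hand-coded
product-limit oracle instead, and the published point estimate is treated as
non-reproducible. The point estimate is seed-free; only the CI resampling
uses the seed (RNG state is restored on exit).

## Synthetic data

`generate_cohort()` draws cohorts with the feasibility study's marginal
structure: truncated-normal age (60.8, 9.3; bounds 18–95, matching the adult
eligibility criterion) and BMI (32.94, 6.13; bounds 15–60), Bernoulli SINBAD
components with probability 0.35 each so the expected total is 2.1, and
reulceration times geometric in a monthly hazard of 0.06 — chosen once so
that roughly 8/15 of a cohort recurs within the 52-week follow-up, the
proportion observed — censored administratively at 364 days. SINBAD totals
and recurrence outcomes are **derived** from the sampled components and
times, never sampled independently of them. A single master seed drives all
streams through fixed offsets, so cohorts, parameter draws and
microsimulations are independently reproducible.

What the generator does *not* emulate: correlations between covariates (age,
BMI and smoking are drawn independently), the recruitment funnel (197
screened to 15 enrolled), non-geometric recurrence hazards, and withdrawal or
loss to follow-up as competing censoring. Passing tests on synthetic data
therefore show the estimators are computed correctly, not that the generator
distributions match real patients.

`simulate_patient_histories()` microsimulates individual paths under the same
transition rules and is the engine's independent stochastic oracle: per-cycle
state frequencies from 100,000 paths agree with the cohort trace within three
binomial standard errors (checked at cycles 1, 12 and 60).

## Numerical choices and test scale

* Trace rows sum to 1 within `1e-9` (property-tested over random validated
  parameter sets); death occupancy is monotone non-decreasing.
* The two-state reduction (post-DFU with constant monthly mortality) matches
  the geometric-series closed form for discounted life-years within `1e-9`.
* The bisection threshold matches a 1,000-point grid-search oracle within one
  grid step across 20 random parameter sets, and re-evaluating at `rr*`
  reproduces the target ICER within relative `1e-5` in tests (the solver's
  own criterion is `1e-6`).
* Problem sizes used by the test suite and acceptance script — 100 random
  parameter sets for mass conservation, 100,000 microsimulated paths, 10,000
  synthetic patients, 1,000-point threshold grids, 2,000-patient KM samples —
  were chosen as the smallest sizes at which the Monte-Carlo bounds above are
  sharp; the full suite runs in well under a minute on a single core.

## Worked example

```{r example}
params <- placeholder_transitions()
econ <- economic_parameters()     # Table of base-case utilities/costs
config <- model_config()

run_scenarios(params, econ, config)
```

On the placeholder set the app needs a 3.9% relative reduction in recurrence
at the 4.99 GBP monthly price, and 3.3% under annual pricing, to reach
20,000 GBP/QALY; the free app dominates trivially. These numbers demonstrate
the machinery on the placeholder inputs — they are not the published
thresholds, which depend on unprinted audit-sourced probabilities.

```{r cohort}
summarize_cohort(dfu_cohort())
```

## Known limitations

* No probabilistic sensitivity analysis (CEAC) — one-way only, by design.
* State-constant mortality (no life tables); results at very long horizons
  should be read accordingly.
* The placeholder transition set is not the published model's input set; the
  published 3%/5% thresholds are consequently not reproduction targets.
* Currency is plain 2017/18 GBP with no inflation machinery.
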