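# dfuheor

Health-economic evaluation tools for interventions that prevent **diabetic
foot ulcer (DFU) recurrence**, aimed at HEOR analysts and researchers working
on digital foot-care tools where comparative effectiveness data do not yet
exist.

## What it does

At its core is a six-state Markov cohort cost-utility model with monthly
cycles. A cohort of recently healed DFU patients (age 67, 70% male) starts in
the *post-DFU* state and can develop a non-severe (SINBAD < 3) or severe
(SINBAD ≥ 3) recurrent ulcer, progress to amputation and post-amputation
care, or die; death is absorbing and amputation is a one-cycle tunnel. State
utilities (0.64 post-DFU, 0.61 non-severe, 0.47 severe, 0.34 amputation,
0.47 post-amputation) and monthly costs (£180.70 / £453.83 / £972.30 /
£1106.19 / £311.96, 2017/18 GBP) follow the published base case; QALYs and
costs are discounted at 3.5%/year with half-cycle correction over a lifetime
horizon.

An intervention with relative recurrence risk *rr* and compliance *c* scales
both recurrence transitions by *rr*·*c* + (1 − *c*). Because no comparative
data exist, the key output is the **threshold analysis**: the relative
reduction 1 − *rr*\* at which the ICER of app-plus-care versus standard care
equals a willingness-to-pay of £20,000/QALY,

ICER = ΔCost / ΔQALY,  NMB = WTP·ΔQALY − ΔCost,  rr\* : ICER(rr\*) = WTP,

solved by bisection on the NMB. Around this sit one-way sensitivity analysis
with tornado ordering, app-pricing scenarios (£0.00 / £4.99 monthly / £4.17
annual), SINBAD severity scoring, feasibility-cohort summary statistics, a
Kaplan–Meier restricted-mean ulcer-free-time estimator with bootstrap CI, and
a synthetic-data module (random transition sets, cohorts, microsimulated
patient histories) that makes every stage testable offline.

Transition and mortality probabilities are **not bundled as real inputs**:
the published model sourced them from audit data and literature without
printing them. `placeholder_transitions()` ships a documented placeholder set
for demos and tests; real analyses supply a YAML parameter file.

## Worked example

```r
library(dfuheor)

params <- placeholder_transitions()
econ   <- economic_parameters()   # base-case utilities, costs, 90% compliance
config <- model_config()          # age 67 -> 100, monthly cycles, 3.5%/yr

run_scenarios(params, econ, config)
#>   scenario app_price_monthly parameter_source          status threshold_rr
#> 1     free              0.00             user dominant_at_rr1    1.0000000
#> 2  monthly              4.99             user              ok    0.9609161
#> 3   annual              4.17             user              ok    0.9673051
#>   relative_reduction_pct     icer
#> 1               0.000000       NA
#> 2               3.908386 20000.18
#> 3               3.269488 19999.89
```

Reading: on the placeholder inputs, a £4.99/month app must cut recurrence by
3.9% (relative risk 0.961) to hit £20,000/QALY; under annual pricing (£4.17)
3.3% suffices; a free app is cost-effective with no effect at all. A cheaper
app always needs less effect, and these placeholder-derived numbers are
demonstrations, not the published thresholds.

The packaged 15-patient feasibility cohort reproduces its printed summaries:

```r
summarize_cohort(dfu_cohort())
#>             statistic     value  n
#> 1      mean_age_years 60.800000 15
#> 2        sd_age_years  9.252027 15
#> 3            mean_bmi 32.940000 15
#> ...
#> 9  n_previous_smokers  9.000000 15
#> 12        n_completed  2.000000 15
#> 13      n_reulcerated  6.000000 15
```

i.e. mean (SD) age 60.8 (9.3) years, BMI 32.94 (6.13), 9/15 previous smokers,
2/15 completers, 6/15 reulcerations.

## Package layout

* `R/` — model core (`transition_parameters`, `run_cohort_trace`,
  `accumulate_outcomes`), economics (`icer`, `nmb`, `threshold_rr`,
  `run_scenarios`), sensitivity (`owsa`), feasibility statistics
  (`sinbad_total`, `classify_severity`, `summarize_cohort`,
  `ulcer_free_time_summary`), synthetic data (`generate_cohort`,
  `generate_transition_params`, `simulate_patient_histories`), IO
  (`load_parameters`, report writers).
* `inst/extdata/feasibility_cohort.csv` — the 15-patient cohort fixture.
* `inst/cli/dfu-heor.R` — subcommand CLI (`run`, `threshold`, `owsa`,
  `cohort-summary`, `simulate`).
* `vignettes/dfu-cost-utility-model.Rmd` — model assumptions, parameter
  meanings, design choices and limitations.
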