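# idioplan

Idiographic treatment planning and process monitoring for single-patient
symptom time series.

## What it does

When a patient answers a short symptom questionnaire several times a day
for a few weeks (ecological momentary assessment), the resulting T × I
time series contains enough structure to rank symptoms by how much
treating them is likely to matter. `idioplan` implements that ranking as a
five-step pipeline:

1. **Exploratory P-factor analysis** — maximum-likelihood factor analysis
   of the item correlation matrix (the "sample" is occasions, not
   persons), direct oblimin rotation, candidates k = 2, 3, 4, each gated
   on the Hu–Bentler criteria (TLI ≥ .95, RMS ≤ .08) with a Bartlett
   sphericity prerequisite; smallest passing k wins.
2. **Confirmatory factor analysis** — items with exploratory loadings
   |λ| > .30 form the confirmatory pattern; ML estimation of
   Σ = ΛΦΛ′ + Θ with free factor correlations, gated on TLI ≥ .95 and
   SRMR ≤ .08.
3. **VAR on factor scores** — factor scores (standardized item data ×
   confirmatory loading matrix) are modeled by per-equation OLS on
   intercept, linear trend, and all factors at lags 1..p, with p ∈ 1..5
   chosen by AIC on a common estimation sample.
4. **Factor scores (planning sense)** — per factor j, the within-time
   share Σᵢ λᵢⱼ²/k² is multiplied by the between-time share (the
   trend-adjusted incremental R² of the lagged block), and products are
   normalized by the maximum, so the most relevant factor scores 1.
5. **Symptom scores** — normalized raw item means × (loading × factor
   score, summed over the item's factors), rescaled so the top symptom
   scores exactly 100.

Any failed gate returns `no_model` with diagnostics instead of a ranking.
The package also ships process-monitoring statistics (moving-window
dynamic complexity C = F·D, recurrence distance matrices, LOESS trend
curves with 95% bands, weekly percent-change outcomes), CSV/YAML I/O for
series and patient configurations, assessment-schedule generation, and a
synthetic-patient simulator with retained ground truth that makes every
stage testable without patient data.

## Worked example

```r
library(idioplan)

truth <- patient_preset("two-factor-dominant")   # known ground truth
sim   <- simulate_patient(truth, T_len = 120, seed = 7)
ts    <- inject_missing(sim$ts, 0.10, seed = 8)  # imperfect compliance

res <- run_planning(ts)
res
```

```
<planning_result> status: found
   stage passed                                                     detail
     efa   TRUE                           k = 2 (TLI = 1.037, RMS = 0.033)
 pattern   TRUE Factor 1 = item1 + item2 + item6; Factor 2 = item3 + ... + item9
     cfa   TRUE                                  TLI = 0.988, SRMR = 0.059
     var   TRUE                                   p = 1, R^2 = 0.206/0.116
  scores   TRUE                                factor scores: 1.000, 0.763
Symptom priority scores (descending):
  item  score
 item2 100.00
 item1  84.58
 item6  81.67
 item4  39.00
 ...
Not modeled (insufficient loadings): item10
```

Reading the output: the two-factor model passed both factor-analytic
gates; the VAR chose one lag; factor 1 (items 1, 2, 6) combines a 54%
within-time share with a 20% between-time share and scores 1, so its most
severe item (`item2`) tops the priority table at 100 — exactly the items
the generator made dominant. `item10`, which loads on nothing, is excluded
rather than scored. `render_report(res, json_path = "report.json")` writes
the same content as JSON.

Command-line wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/simulate.R --preset two-factor-dominant --T 120 --seed 7 --out series.csv
Rscript inst/cli/plan.R --input series.csv --config patient.yml --out report.json
Rscript inst/cli/monitor.R --input series.csv --config patient.yml --item item2 --window 7
```

`plan.R` exits 0 when a model is found, 3 on `no_model`, 2 on input
errors.

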