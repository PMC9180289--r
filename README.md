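# metnorm

Meteorological normalization ("de-weathering") of daily particulate-matter
time series, for air-quality researchers who need to ask whether an
intervention — a COVID-19 lockdown, a traffic ban, a heating regulation —
actually changed pollutant levels once weather and long-term trends are
accounted for.

Day-to-day PM₁/PM₂.₅/PM₁₀ mass concentrations are dominated by meteorology:
wind disperses, rain washes out, cold spells trap emissions and switch
heating on. Comparing an April under lockdown with the previous April
therefore mostly compares two Aprils' weather. The normalization approach
used here removes that variation:

1. **Model.** Fit a tree-ensemble regression `PM ~ f(met, time)` per
   fraction, where the predictors are 14 daily meteorological aggregates
   (max/min/diff/avg of temperature, pressure, relative humidity; wind
   speed; precipitation) and 5 temporal variables (weekday, Julian day,
   month, year, holiday flag). Two families are tuned by Gaussian-process
   Bayesian optimization over temporal-block cross-validation — a random
   forest and leaf-wise gradient-boosted trees — and the winner per
   pollutant is chosen by RMSE on a held-out validation window.
2. **Normalize.** Repeatedly (default 100×) permute every predictor column
   except the Julian-day trend variable, predict, and average:
   `PM*(d) = (1/n) Σᵢ f(julian(d), Xᵢ)`, where each `Xᵢ` is a random
   within-column permutation of the observed predictors. The average over
   counterfactual weather leaves the long-term (trend) component.
3. **Compare.** Summarize the normalized series by yearly medians inside
   named analysis windows — pre-lockdown (CS: 3 Jan–29 Feb), lockdown
   (LDS: April), "new normal" (NNS: June–July) — after excluding
   out-of-ordinary events (earthquake, desert-dust transport flagged by
   PM₁₀/PM₂.₅ and PM₁₀/PM₁ ratio screening, construction), and test yearly
   differences with one-way ANOVA (year as categorical factor).

Because real deposited measurements are not bundled, the package includes a
first-class synthetic generator (`generate_daily_dataset()`) producing
12-year daily records with known trend, seasonality, weekday structure,
weather coupling, dust spikes, gaps and an optional step intervention — so
every stage is testable by parameter recovery.

## Worked example

The analysis is organized as numbered drivers over the package functions:

```sh
Rscript analysis/01_simulate.R        # 12-year synthetic record + ground truth
Rscript analysis/02_prepare.R        # ratio screen, imputation, features, splits
Rscript analysis/03_train_normalize.R # tune/train/select, de-weather
Rscript analysis/04_compare.R        # yearly medians + ANOVA + trend recovery
```

Step 2 flags exactly the planted dust episode (plus one borderline day):

```
ratio screen: 6 day(s) flagged; thresholds pm10/pm25 1.62, pm10/pm1 3.53
flagged dates: 2009-05-26, 2020-03-26, 2020-03-27, 2020-03-28, 2020-03-29, 2020-03-30
```

Step 3 selects a winner per fraction on the Jan–Mar 2020 validation window
(families split, as they do on real data):

```
pm25: winner random_forest (validation RMSE 4.14, R2 0.76)
pm10: winner gradient_boosted_trees (validation RMSE 4.12, R2 0.83)
```

Step 4 prints the period comparison. The simulated record has no
intervention but a genuine downward trend (−0.8 µg/m³/yr for PM₂.₅), so
"year" is a real effect in some windows, and the recovered April trend can
be checked against the generator's ground truth:

```
  pm25  LDS  F(2, 87) =   6.448  p = 0.0024  SIGNIFICANT  medians: 2018: 26.13, 2019: 25.65, 2020: 25.27
  pm25  NNS  F(2,180) =   0.311  p = 0.7334  n.s.         medians: 2018: 25.77, 2019: 25.69, 2020: 25.68
pm25: recovered April trend -0.58 ug/m3/yr (injected -0.80)
```

The same machinery is available as one call:

```r
library(metnorm)
report <- run_pipeline(list(
  seed = 1,
  data = list(synthetic = list(met = list(n_years = 4, start_date = "2017-01-01"))),
  fractions = "pm25",
  model = list(cv_folds = 3, opt_budget = 10, spaces = "reduced"),
  normalization = list(n_samples = 25),
  train_years = 2017:2019, years = 2018:2020
), "run_out")
```

which writes the daily record, normalized series, model scoreboard, ANOVA
report (JSON + text) and a reproducibility manifest into `run_out/`;
re-running the same config reproduces every file byte for byte.

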