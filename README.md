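# bloomsense

Chlorophyll-a soft-sensing and harmful-algal-bloom (HAB) alarm evaluation
from high-frequency buoy data, in R.

## The problem

Chlorophyll-a (Chl-a) fluorescence is the operational proxy for algal and
cyanobacterial biomass in freshwater reservoirs: the WHO level-1 management
alert is reached at 10 µg/L. Fluorescence probes are the costly,
maintenance-heavy part of a monitoring buoy, while water temperature,
electrical conductivity (EC), pH and the system battery voltage are cheap
and robust. A *soft-sensor* is a regression model that infers Chl-a from
those four channels, turning any basic multiparametric buoy into a bloom
early-warning device.

bloomsense is for limnologists, water managers and monitoring engineers
who want to build and honestly evaluate such soft-sensors. It provides:

* **Cleaning** — per-variable physical limits with the two-step rule:
  values up to 5% of the range span outside a limit are snapped to the
  boundary; rows with values beyond that band, or missing, are dropped.
* **Feature augmentation** — trailing (causal) 1-h and 24-h window
  statistics (mean, std, median, min, max) per input variable, giving the
  four input variants `input_orig`/`input_hour`/`input_day`/`input_mix`
  (4/24/24/44 features), and five target variants (instantaneous Chl-a or
  its 1-h/24-h trailing mean/median) — a 20-cell experiment grid.
* **Leakage-safe normalization** — Yeo-Johnson power transform plus
  standard scaler, fitted per fold on training chunks only and frozen.
* **Chunked temporal K-fold** — the dataset is cut, unshuffled, into K
  contiguous chunks; each hyperparameter configuration is K models, each
  trained on K−1 chunks and validated on the held-out one; random search
  (L2 ∈ [10⁻⁴, 1] log-uniform; tree depth ∈ [1, 500]; estimators
  ∈ [2, 200]) ranks configurations by mean validation MAE,
  MAE = (1/n) Σᵢ |yᵢ − ŷᵢ|.
* **Model families** — ridge linear regression, unpruned CART, random
  forest, and the training-mean baseline.
* **Alarm evaluation** — out-of-fold predictions thresholded at 10 µg/L;
  precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = their harmonic mean;
  reported with MAE/MSE/MAE-STD overall, per buoy, and per calendar month
  (pooling every year's occurrence of each month).
* **Feature importance** — impurity-based RF importance shares next to
  Pearson correlations, with the named reduced sets `3-AGG`
  (pH_day_max, Temperature_day_min, SystemBattery_day_min) and `5-AGG`
  (+ Conductivity_day_max, pH_day_min).
* **A synthetic two-buoy generator** — seasonal September-peaking blooms,
  diel pH/temperature cycles coupled to algal activity, rain/drought
  conductivity shifts, a solar charge cycle, sensor noise, fluorescence
  spikes, out-of-range outliers and missing samples — so the whole
  pipeline is testable without any download, and parameter recovery is
  checkable against ground truth.

Everything takes and returns tibbles, chains with the pipe, and has
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Three synthetic years at 4-hour cadence, corrupted, cleaned, then the
day-aggregated input variant against the day-median Chl-a target with
K = 5 chunked validation and 3 random configurations per family:

```r
library(bloomsense)

cfg <- synthetic_config(n_years = 3, cadence_min = 240,
                        spike_rate = 0.01, seed = 1)
sim <- simulate_buoys(cfg) |> inject_artifacts(seed = 2)
rec <- clean_records(sim$records)$records

exp <- run_experiment(rec, "input_day", "output_day_median",
                      families = c("baseline", "lr", "cart", "rf"),
                      k = 5, n_configs = 3, seed = 3)
exp
#> <soft_sensor_experiment> input_day x output_day_median, 12494 rows
#>    family     n  mae    mse mae_over_std   tp   fp   fn   tn precision recall
#>  baseline 12494 8.97 178.30       0.6967  295 4703 3097 4399     0.059  0.087
#>      cart 12494 1.54  13.31       0.1198 3182  169  210 8933     0.950  0.938
#>        lr 12494 3.82  76.02       0.2968 3352 1042   40 8060     0.763  0.988
#>        rf 12494 1.16   9.61       0.0899 3280  153  112 8949     0.955  0.967
#>      f1
#>  0.0703
#>  0.9438
#>  0.8610
#>  0.9612
```

Reading the table: the random-forest soft-sensor reproduces the day-median
Chl-a with a mean absolute error of 1.16 µg/L (an eighth of the
baseline's 8.97 µg/L) and triggers the 10 µg/L level-1 alarm with
F1 = 0.96 — 3280 true alarms caught, 153 false alarms, 112 missed — while
the linear model, which tracks the mean but not the bloom outliers, sits
in between. On the *instantaneous* target the same setup gives RF
5.48 µg/L vs baseline 11.34 µg/L: aggregating the output to a day-median
removes ephemeral fluorescence spikes from the quantity being predicted
and improves every family.

Per-month and per-buoy views, importance, and plots:

```r
monthly_breakdown(exp$oof |> dplyr::filter(family == "rf"))
rf <- fit_soft_sensor(exp$dataset, family = "rf",
                      config = list(max_depth = 25, n_estimators = 60))
feature_importance(rf, exp$dataset)   # pH-derived features rank first
autoplot(exp$oof)                     # observed vs inferred, alarm line
```

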