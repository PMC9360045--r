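---
title: "Methods: a chlorophyll-a soft-sensor with chunked temporal validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a chlorophyll-a soft-sensor with chunked temporal validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chlorophyll-a (Chl-a) fluorescence is the standard proxy for algal and
cyanobacterial biomass in freshwater reservoirs, and the variable on which
harmful-algal-bloom (HAB) management thresholds are defined — the WHO
level-1 alert corresponds to 10 µg/L. Fluorescence probes, however, are the
expensive, maintenance-hungry part of a monitoring buoy. A *soft-sensor*
replaces the probe with a regression model that infers Chl-a from the cheap
channels a buoy logs anyway: water temperature, electrical conductivity
(EC), pH and the system battery voltage (a daylight/season proxy on
solar-powered buoys). bloomsense implements that pipeline end to end:
cleaning, moving-window feature augmentation, per-fold normalization,
order-preserving chunked K-fold model selection, and regression plus alarm
evaluation per buoy and per calendar month.

Everything user-facing is a tibble in and a tibble out, so stages chain
with the pipe; fitted objects have `tidy()`/`glance()` methods and result
types have `autoplot()` methods.

## Cleaning

Raw records are validated against per-variable physical limits
(`valid_ranges()`). With limits $[lo, hi]$ and span $s = hi - lo$, a value
in $(hi, hi + 0.05\,s]$ or $[lo - 0.05\,s, lo)$ is *snapped* to its nearest
boundary — a small calibration offset, the measurement is still usable — and
a row holding any value beyond that 5% band, or a missing value, is removed
whole, since a gross excursion indicates sensor failure and discredits the
entire record. Cleaning is idempotent, preserves the order and timestamps
of kept rows, and reports snap counts per variable and the removal
fraction.

Two readings of "5% of the limits" are defensible (5% of the span versus 5%
of each limit value); only the span reading is well defined for variables
whose lower limit is 0, so that is the implemented rule, with the tolerance
fraction exposed as configuration. The shipped limits (pH [0, 14],
temperature [−5, 50] °C, EC [0, 2000] µS/cm, battery [0, 20] V, Chl-a
[0, 500] µg/L) are plausible sensor ranges, not normative constants.

## Feature and target variants

Each input variable is augmented with five descriptive statistics — mean,
sample standard deviation, median, minimum, maximum — over trailing windows
of 1 hour and 24 hours, producing four input variants: `input_orig` (4
features), `input_hour` and `input_day` (4 + 5·4 = 24 each) and
`input_mix` (44). The target has five variants: instantaneous Chl-a or its
1-h/24-h trailing mean or median. Crossing them gives the 20-cell
experiment grid (`experiment_grid()`).

Three numerical choices deserve attention:

* **Windows are duration-based, not row-count based.** Cleaning removes
  rows; a 96-row window would silently stretch across gaps while a 24-h
  window keeps its physical meaning. The `(t - W, t]` interval always
  contains the current sample, so the window is never empty; partial
  windows at a series start (or after a gap) use whatever samples exist,
  and `rolling_stats()` emits a per-row in-window count for audit.
* **All windows are trailing (causal), for the target too.** A centred
  window on the output would leak future observations into the quantity
  the soft-sensor is trained to reproduce.
* **Aggregation never mixes buoys**: statistics are computed per `buoy_id`
  group.

The rolling kernel is a small C++ routine (two-pointer sweep over the
time-sorted series); its only contract is equality with brute-force
recomputation over explicitly collected in-window samples, which the test
suite asserts on randomly gapped series. A single-sample window reports a
standard deviation of 0 (the sample formula is undefined at n = 1, and 0
is the only value consistent with "no observed spread").

## Normalization

Features are passed through a Yeo-Johnson power transform (chosen over
Box-Cox because it is defined for zero and negative values — battery or
temperature anomalies can be non-positive) followed by a standard scaler.
Linear models benefit; trees are indifferent but are normalized anyway so
every family trains on identical inputs. The transform parameters and
center/scale are estimated on training-fold rows only and then frozen;
`apply_normalizer()` never re-estimates. Zero-variance columns get a unit
scale (with a warning) rather than an error, since a constant sensor
channel is a data problem, not a programming one. Parameter estimation is
delegated to `caret::preProcess(method = "YeoJohnson")`; standardization is
done in-package to guarantee the zero-variance convention. An affine-only
mode (`power_transform = FALSE`) exists chiefly so exact-linear-recovery
properties can be asserted to numerical precision.

## Model families

* `lr` — linear regression with an L2 (ridge) penalty on the slopes,
  intercept unpenalized, solved exactly by the normal equations at the
  configured coefficient.
* `cart` — an unpruned squared-error regression tree (rpart with `cp = 0`,
  `minsplit = 2`, `minbucket = 1`) grown to the configured depth. rpart
  caps depth at 30; sampled depths up to 500 are truncated there, which is
  immaterial because a depth-30 tree with unit leaves already has more
  capacity than any dataset this pipeline sees.
* `rf` — a random forest of such trees (ranger), bootstrap-resampled, with
  a random feature subset per split of ⌊p/3⌋ (the regression convention;
  `mtry_fraction` is configuration) and a minimum node size of 5.
* `baseline` — the constant training-mean predictor; any model worth
  deploying must beat it.

Hyperparameters are tuned by random search over: L2 coefficient in
[10⁻⁴, 1] (log-uniform — the range spans four decades, and uniform sampling
would all but ignore the lower decades), tree depth in [1, 500], and
estimator count in [2, 200], uniform integers. The full design — 20 grid
cells × 25 configurations × 3 tunable families — is 1500 settings, and with
K = 10 folds each, 15 000 scheduled model fits (`search_budget()`).

Because the CART and RF implementations come from different libraries, the
"RF with one tree equals its CART" identity is not testable literally
(rpart and ranger break ties differently); the suite instead verifies the
degenerate-ensemble property (with bootstrap and feature subsampling
disabled, all ranger trees are identical and the ensemble equals a single
tree) and the depth-monotonicity of CART training error.

## Chunked temporal validation

Random train/test splits overfit badly on autocorrelated series, and a
plain first-two-years/last-year split tests each calendar month only once.
The compromise implemented here: the pooled, time-sorted dataset is cut
into K = 10 contiguous, near-equal chunks (never shuffled); each
configuration is represented by K models, each trained on K − 1 chunks and
scored on the held-out chunk; a configuration's score is the mean of its K
validation MAEs. Out-of-fold predictions for the winning configuration —
each row predicted by the one model that held its chunk out — form the test
surface, partitioned afterwards by buoy and calendar month so a three-year
record yields three pooled occurrences of every month.

Design choices within that scheme:

* Both buoys are pooled for chunking and search (reporting is split per
  buoy afterwards); filtering the dataset before `run_search()` gives
  per-buoy training when wanted.
* The normalizer depends only on the fold, so it is fitted once per fold
  and shared across configurations — identical results, 25× fewer
  Yeo-Johnson fits.
* Ties in mean MAE resolve toward the less complex configuration (fewer
  estimators, then smaller depth, then smaller L2), then sampling order,
  so leaderboards are deterministic.
* Two test-surface conventions are defensible: assembled out-of-fold
  predictions, or a single reserved chunk never touched by the search.
  The default is the out-of-fold reading — it is the only one that tests
  every calendar month in all of its yearly occurrences — and
  `holdout_chunk =` implements the reserved-chunk alternative.
* Every stochastic step takes a seed derived from the call's master seed,
  so runs are reproducible end to end.

## Alarm evaluation

Predicted and observed series are thresholded at 10 µg/L (strict `>` by
default; the "equal or higher" reading is `inclusive = TRUE` — the
difference only matters for values exactly on the boundary). Precision,
recall and F1 are computed from the confusion matrix per group; a zero
denominator leaves precision/recall undefined (`NA`) and F1 is reported as
0, keeping tables machine-comparable. Alarm truth uses the *same* output
variant as the regression target, so each aggregation experiment is
evaluated self-consistently: a day-median model is judged on day-median
exceedances. Vigilance (1 µg/L) and level-2 (50 µg/L) thresholds can be
passed to `alarm_flags()` but play no role in model selection. Regression
quality is reported as MAE, MSE and MAE/STD — the latter scales MAE by the
spread of the observed target, which keeps aggregated and raw targets
comparable (aggregation shrinks the spread, so raw MAE alone would flatter
it).

## The synthetic generator

`simulate_buoys()` emulates the couplings a chlorophyll soft-sensor
exploits, at 15-min cadence over three years by default, for two buoy
profiles ("beach": shallow, noisier; "dam": deeper, with a markedly larger
diel Chl-a swing from vertical migration):

* latent Chl-a = seasonal Gaussian envelope (peak near day-of-year 248,
  early September) + log-normal bloom pulses centred on late summer
  (blooms are ephemeral — hours to days — so pulses, not the envelope,
  carry most of the variance) × a diel modulation;
* pH = base + 0.35·log1p(latent Chl-a) + diel term + noise — the
  photosynthesis coupling, saturating so pH stays physically plausible;
* temperature = seasonal + diel sinusoids + noise;
* EC = baseline + drought (late-summer) drift − exponentially decaying
  rain-event dips + noise;
* battery = daylight-driven charge/discharge sawtooth with season-dependent
  night length, so the daily battery minimum encodes season;
* the Chl-a channel adds sensor noise and, at `spike_rate`, ephemeral
  in-range fluorescence-interference spikes (what day-median aggregation
  is supposed to filter).

Default artifact rates (`inject_artifacts()`: 4% outliers, half just inside
the 5% snap band and half beyond, plus 3% missing) make default cleaning
remove 5% of rows. At most one artifact is planted per row so planted
counts equal the cleaning report's tallies exactly.

What the generator does *not* emulate: hydrodynamics (thermocline physics,
mixing), nutrient limitation, sensor drift and biofouling, cross-buoy
spatial correlation, and real outage patterns. Tests passing on this data
therefore demonstrate that the pipeline recovers planted structure under
realistic noise — not that any particular accuracy will transfer to a real
reservoir.

## Problem sizes used by the tests and the acceptance script

The generator's defaults describe the full deployment (3 years, 15-min,
two buoys ≈ 210 000 rows). The test suite and `scripts/acceptance.R`
exercise the identical code paths at reduced size, which the package
treats as its standard validation configuration: three synthetic years at
4-h cadence (≈ 13 000 rows over two buoys) for the model-fitting
comparisons with K = 5 and 3 sampled configurations per family; three
years at 6-h cadence for the calendar-pooling and leakage checks; and the
full 15-min grid only where row-count arithmetic itself is under test.
The reduction keeps the cadence coarse rather than the record short: with
a single simulated year, a held-out contiguous chunk is seasonally
out-of-distribution and tree models — which cannot extrapolate beyond
their training target range — degrade toward the baseline, whereas the
multi-year record preserves the month-recurrence property the chunked
validation is designed around (every month's occurrences in other years
remain in training). Structural counts (20 variants, 1500 settings,
15 000 scheduled fits) are computed by enumeration, not by training.

## Known limitations

* No gap imputation, drift correction or calibration against grab samples;
  rows are either trusted (possibly snapped) or discarded.
* The level-2 (50 µg/L) alarm is exposed only as a threshold option;
  exceedances that rare need different modelling.
* `rpart`'s depth-30 ceiling truncates the nominal [1, 500] depth range
  for CART (not for RF).
* Walk-forward (expanding-window) validation and nested CV are out of
  scope; the chunked K-fold here selects hyperparameters and reports
  out-of-fold performance from the same folds.
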