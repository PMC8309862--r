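---
title: "Forecasting pest insect appearance from temperature and humidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting pest insect appearance from temperature and humidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adult moths of polyphagous pests such as the cotton bollworm
(*Helicoverpa armigera*) are monitored with traps scattered over a
region. Checking traps is expensive; air temperature and relative
humidity, which drive moth activity, are cheap and available daily from
any weather station. `pestcast` predicts, for each location and day,
whether the pest will appear (at least one trapped insect), using only
the day of year and the last ten days of temperature and humidity, and
scores those predictions the way an agronomist would use them: a
predicted appearance is still useful if the insect actually arrives a
day or two later, because control acts on the moth and egg stages over
a window of several days.

## The model

Each day $d$ of a location-season series contributes one sample with 21
features: the day of year and the lagged values
$T_d, T_{d-1}, \dots, T_{d-9}$ and $RH_d, \dots, RH_{d-9}$. Lag windows
never span gaps in the record: a missing day splits the series into
segments and the first nine days of each segment yield no sample. The
current day's weather is deliberately part of its own feature window
(the reference configuration of the method); `forecast_lag` shifts the
whole window into the past for strict ex-ante forecasting.

Nine standard classifiers form the bank: 3-nearest neighbours,
polynomial-kernel SVM ($C = 10$, degree 3, `scale` kernel coefficient),
RBF SVM ($C = 1$, $\gamma = 2$), a Gini decision tree of depth 5, a
random forest of ten depth-5 trees, a one-hidden-layer perceptron of
width 100 (weight decay 1, at most 1000 iterations), Real AdaBoost over
50 decision stumps, Gaussian naive Bayes, and QDA. The hyperparameters
live in a registry (`list_models()`), not in code. Features are *not*
standardized by default — the reference configuration uses raw units —
which is why the RBF SVM with $\gamma = 2$ per squared degree-or-percent
is expected to degenerate towards the majority class on realistic data;
it is kept in the bank because pruning it is the job of the selection
rule, not of the configuration.

Two backends deserve a note. The perceptron is fitted with `nnet`
(logistic hidden units, full-batch BFGS); width, decay and the iteration
cap follow the registry, but the activation and optimizer differ from
mini-batch relu/adam implementations, so its decision boundary is an
architectural analogue rather than a numerical twin. AdaBoost is
implemented in the package itself as two-class Real AdaBoost (the
probability-weighted variant, equivalent to SAMME.R for two classes)
over weighted depth-1 `rpart` stumps, because no adaptive-boosting
package is available; each round converts the stump's class-1
probability to a half-log-odds score and reweights exponentially, and
the committee predicts the sign of the summed scores.

### Splits

Model comparison uses a seeded random 75/25 split of the pooled
samples. The held-out evaluation uses a *chronological* split: within
each location-season, the first $\lceil 0.75\,m \rceil$ samples train
and the rest test, so every test day follows every training day of its
series and no lag window leaks future information. The split is
per-series rather than global because a global date cut would let one
location's training window overlap another's test dates.

### Model selection

On the random-split validation confusion counts, a model is excluded
if (a) its false positives exceed its true positives — it raises more
false alarms than detections — or (b) its TP count is below a
configurable fraction (default 0.5) of the best model's TP. The second
rule makes a qualitative judgement ("low TP") quantitative; the
fraction is exposed because no canonical value exists.

### Windowed verification

With $P_d, R_d \in \{0, 1\}$ the predicted and real labels, the
same-day hit accuracy is
$\mathrm{AD} = \mathrm{numD}/\mathrm{numR}$ where $\mathrm{numD}$ is
the number of days with $P_d = R_d = 1$ (equal to TP) and
$\mathrm{numR}$ the number of real occurrence days (TP + FN). The
extended statistic credits a predicted-positive day $d$ if a real
occurrence falls anywhere in $d, \dots, d + w - 1$ ($w = 3$ or $5$):

    IF P_d = 1 and (R_d = 1 or ... or R_{d+w-1} = 1) THEN hit

Windows are forward-only, truncate at the end of each location-season,
and never cross series boundaries — crediting a hit across a winter gap
or another location would be biologically meaningless. Every
predicted-positive day is judged independently; several predicted days
may be credited to the same occurrence day, so the windowed hit
accuracy can exceed 1. It is reported as computed, never clipped, and
the report surfaces it next to the conservation identity
$\mathrm{numD}_w + \mathrm{FP}_w = \mathrm{TP} + \mathrm{FP}$, which
holds for every $w$. At $w = 1$ the statistic reduces exactly to
(TP, FP). Both of these, plus the monotonicity of hits and false
predictions in $w$, are theorems of the definitions and are asserted as
properties in the test suite.

The false-prediction rate has no canonical denominator: the package
computes it per real occurrence day ($\mathrm{FP}_w/\mathrm{numR}$, the
default, matching how false detections are usually quoted against the
number of real events) and per predicted-positive day
($\mathrm{FP}_w/(\mathrm{FP}_w + \mathrm{numD}_w)$). Both appear in the
report; neither is privileged beyond the default.

Degenerate conventions: precision is 0 when nothing was predicted
positive, recall 0 when nothing occurred, F1 = 0 when precision +
recall = 0, and the windowed accuracy is reported as not applicable
(`NA`) when the series has no occurrence day.

## The synthetic generator

Real multi-year trap datasets are rarely public, so the package ships a
generator with known ground truth. Temperature follows an annual
sinusoid (mean 17 °C, amplitude 9 °C, peak around day 199) plus AR(1)
noise (coefficient 0.6, innovation SD 2.5 °C) started from its
stationary law — day-to-day persistence is what makes 10-day means
informative. Humidity is coupled negatively to temperature
(−1.5 % per °C around a 70 % base) with independent noise (SD 8 %),
clipped to [0, 100]. Occurrence on an eligible day is Bernoulli with a
logistic hazard in the *10-day trailing means* of temperature and
humidity, so the generative signal lives exactly in the feature window
the pipeline extracts and parameter-recovery tests are meaningful. The
first nine days of each season are labelled 0 rather than missing: they
can never become samples, and a total schema keeps the CSV simple.

Defaults emulate a 17-location, two-season (April–October) monitoring
network. The hazard slopes (2.5 per °C, 0.25 per %) are deliberately
sharp so that hazards cross 0.5 on occurrence-prone days — a bank whose
best member reaches recall near 0.8 is only possible on data where the
optimal rule sometimes predicts an appearance — and the intercept
(−81.6) was calibrated once so the mean hazard over eligible days is
9.3 %, the strong class imbalance characteristic of trap data (roughly
one occurrence day in eleven). Each (location, season) pair draws from
its own RNG stream derived from the master seed, so enlarging the
network never perturbs existing series.

What the generator does *not* emulate: spatial correlation between
locations, mechanistic population dynamics (degree-day accumulation,
stage structure, diapause), multi-day trap-emptying artefacts, sensor
dropout, and within-season autocorrelation of the labels beyond what
the weather induces. Passing recovery tests therefore show that the
pipeline extracts a weather-coded signal correctly — not that any
classifier would reach comparable accuracy on field data.

Because the hazards are known, the generator also yields the Bayes
ceiling: predict appearance iff $p_d > 0.5$, with expected accuracy
$\mathrm{mean}(\max(p_d, 1 - p_d))$. The recovery benchmark (20
locations, 8,200 samples) requires every retained classifier's
chronological-test accuracy to come within 5 percentage points of that
ceiling computed *on the test-window days* — the late-season test
window has its own hazard distribution, so comparing against the
all-season ceiling would mix populations. The zero-signal null
(slopes 0) checks the other side: no classifier may beat the
majority-class rate by more than three Monte-Carlo standard errors.

## Numerical and design choices

- **Split arithmetic.** The random split assigns `round(0.75 n)`
  samples to training; the chronological split gives training the
  boundary sample (`ceiling`). Both are deterministic; the asymmetry
  follows the respective conventions of shuffled and ordered splits.
- **CSV schema.** `location_id,date,temperature_c,relative_humidity_pct,occurrence`,
  ISO dates, `.` decimal, empty field for missing occurrence. Simulated
  weather is rounded to 0.001 so `read(write(x)) == x` exactly and
  rewrites are byte-identical.
- **Seeds.** Every stochastic step (simulation streams, the random
  split, forest/perceptron training, KNN tie-breaking) is wrapped in
  its own derived seed; a run directory's config snapshot reproduces
  all outputs byte for byte.
- **Percentages** in summaries are printed to one decimal place.
- **Problem sizes** used by the shipped checks: the recovery benchmark
  uses 8,200 samples, the oracle-equivalence suite 1,000 random series
  of 25 days, the zero-signal null 606 samples. These are the sizes at
  which the stochastic tolerances above are meaningful.

## Known limitations

- The bank predicts from each day's feature vector independently; no
  sequence model carries temporal state between days (an HMM/RNN-style
  extension is out of scope here).
- The default configuration includes the predicted day's own weather in
  its features; for operational early warning use `forecast_lag > 0`
  and expect lower accuracy.
- `nnet`'s optimizer differs from mini-batch implementations of the
  same architecture; its per-run results should be compared within this
  package only.
- The windowed hit accuracy is not a proper scoring rule and can exceed
  1; it answers "how many flagged days were vindicated within w days",
  not "how well calibrated is the forecast".

## A worked miniature

```{r, eval = FALSE}
library(pestcast)
fx <- make_fixtures(tempdir())          # 2 locations x 60 days, seed 42
readLines(file.path(fx$run_dir, "summary.txt"))
```

The fixture run trains the bank on a random 75/25 split, prunes it with
the exclusion rule, re-trains the survivors chronologically and prints
a summary whose windowed block shows the characteristic pattern: hits
non-decreasing and false predictions non-increasing as the window grows
from 1 to 3 to 5 days.
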