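---
title: "One-class k-means ensembles for wearable-sensor risk detection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class k-means ensembles for wearable-sensor risk detection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ockra)
```

## The problem

Personal risk detection asks whether the signals streaming from a wearable
band — tri-axial acceleration and angular velocity, heart rate, pedometer,
distance, calories, skin temperature, UV exposure — currently look like the
wearer's ordinary behavior or like something abruptly different (a fall, a
sprint away from danger, a breathing crisis). Only *normal* data are available
for training: nobody collects a labeled library of their own emergencies. This
is one-class classification: model the positive (normal) class, score new
observations by conformity, and alarm on low conformity.

## The ensemble model

`ockra()` trains an ensemble of `n_members` (default 100) independent
one-class members on a feature matrix of `n` columns. Member $i$:

1. **Random feature selection with replacement.** Draw $n$ indices uniformly
   from $\{1,\dots,n\}$ and deduplicate. The expected retained fraction is
   $1-(1-1/n)^n$, about 63.9% for $n = 26$ and $\to 1 - 1/e \approx 63.2\%$
   for large $n$. This is the diversity mechanism, in the spirit of random
   subspace methods and random forests.
2. **Projection.** Keep only the selected columns.
3. **Distance threshold $\delta_i$.** Subsample the projected rows so kept
   rows are at least 60 s apart (about $m/60$ rows of an $m$-row log) and set
   $\delta_i$ to the mean Euclidean distance over all unordered pairs of kept
   rows. The subsampling breaks the strong second-to-second autocorrelation
   of wearable data and keeps the pair computation cheap.
4. **k-means++ clustering.** Fit `k` (default 10) centroids on the projection
   (k-means++ seeding, then Lloyd iterations) and store them.

A query row is scored per member by a Gaussian kernel of the Euclidean
distance $d_{\min}$ to the member's nearest centroid,

$$ s_i = \exp\left(-\tfrac12 (d_{\min}/\delta_i)^2\right), $$

and the ensemble score is the member mean. Scores live in $[0,1]$: 1 means
the query coincides with a centroid in every member; values near 0 flag a
risk-prone observation. At $d_{\min}=\delta_i$ the kernel gives
$e^{-1/2}\approx 0.607 > 0.6$, and at $d_{\min}=3\delta_i$ it gives
$e^{-9/2}\approx 0.011 < 0.02$ — the kernel form is fixed by exactly these
two bounds, which is also why the exponent is $(d/\delta)^2$ rather than any
of the other readings of the same symbols.

Deployment-motivated constants: 100 members of 10 centroids mean a trained
model is 1000 small vectors — two orders of magnitude cheaper at query time
than a Parzen window over the full training log, which matters on a phone.
Neither 100 nor 10 is claimed optimal; both are kept as the established
defaults.

### Numerical choices

* Per-member RNG: member $i$ uses a child seed drawn from the master seed, so
  training is reproducible and members are order-independent.
* Lloyd iterations cap at 100 with convergence at a maximum centroid shift
  below $10^{-6}$; an emptied cluster seizes the point farthest from its
  current centroid.
* Fewer than `k` distinct rows fit `k' = #distinct` centroids instead of
  failing, so tiny fixtures remain usable.
* Degenerate $\delta = 0$ (constant training data) is floored at $10^{-12}$:
  identical queries still score 1, anything else scores ~0.
* Nearest-centroid ties break to the lowest centroid index.
* No feature scaling anywhere: distances are computed on raw features. This
  is deliberate and matches the method family; its consequence — features
  with large numeric ranges (pace in ms/m, speed in cm/s) dominate the
  Euclidean geometry — is visible in the scenario analyses below.

## Preprocessing

`build_feature_vectors()` turns a raw multi-rate log (rows of `timestamp`,
`channel`, `value`) into one 26-field vector per second: channels faster than
1 s (the three tri-axial motion blocks at 8 Hz) contribute the window mean and
sample standard deviation ($n-1$ denominator; 0 for a single sample); 1 Hz
channels contribute the raw value; slower channels carry the last observation
forward; cumulative counters (steps, distance, calories) contribute the
increment over the previous second. A second with no high-rate sample — a
battery gap — emits nothing: gaps are absences, not zeros. The increment
reference resets after gaps longer than 120 s so recharging never produces a
spurious jump. UV exposure categories map to the ordinal code
none/low/medium/high/very high → 0–4.

Five-fold splitting (`split_folds()`) uses contiguous temporal blocks rather
than row shuffling, preserving the time-series nature of the log; each
repetition tests on one held-out block joined with the full anomaly set, and
anomaly rows never enter training.

## Baselines

All distance-based baselines share the ensemble's kernel and its 60-s width
rule, so the methods differ only in their reference sets: the Parzen window
classifier keeps every training row; `kmeans1` keeps `k` k-means++ centers and
scores by the nearest one; `kmeans2` scores by the mean kernel over all
centers. With one center per training point `kmeans2` reduces exactly to
Parzen, and `kmeans2 <= kmeans1` always (a mean never exceeds a maximum).
The original baseline publications do not print their kernel, so the shared
form is a documented assumption chosen for comparability. The one-class SVM
is an adapter over libsvm (`e1071`), RBF kernel, $\gamma = 0.038$,
$\nu = 0.5$, no scaling; it is a contract, not a re-implementation.

## Evaluation

Anomaly is the positive class and a query is called positive when its score is
at or below the threshold (scores are similarities; the orientation follows
from 0 meaning risk). ROC and P-R curves come from one sorted threshold sweep
with tied scores collapsed to a single operating point; AUC is the trapezoidal
area and equals the normalized Mann-Whitney statistic, which the tests verify
on random fixtures. Per-subject AUC pools the scores of the five
cross-validation rounds before building one curve (the alternative,
averaging per-fold AUCs, was noted and not taken — one curve per subject
matches how the benchmark table is reported). Population curves use vertical
averaging on a 101-point grid. The paired Wilcoxon signed-rank comparison
drops zero differences and uses the exact distribution up to 25 informative
pairs (normal approximation beyond, or under ties); Kruskal-Wallis tests
whether subjects' distributions are exchangeable, which on the benchmark they
are not — the reason the whole pipeline is subject-dependent.

The published 23-subject AUC table is shipped as a CSV fixture
(`pride_auc_table()`); its column means reproduce its printed Average row to
two decimals, and the ensemble's average lead over the best competing column
is 0.53 AUC points on those printed averages. The underlying wearable dataset
is restricted, so the absolute AUC values are *not* reproduced by this
package; the fixture exercises the report arithmetic and the paired tests.

## The synthetic generator

The real benchmark data are available only on request, so the package ships a
generator (`simulate_normal_log()`, `simulate_anomaly_log()`,
`generate_dataset()`) whose contract is statistical structure, not
physiological fidelity: multi-rate channels at the band's native rates,
battery-gap discontinuities, a hidden rest/walk/brisk activity chain
modulating motion variance, cadence, speed and heart-rate level, a circadian
heart-rate sinusoid, and five staged anomaly scenarios.

Design choices, fixed once:

* **Rest-heavy mixing.** The activity chain targets roughly 70% rest, 20%
  walking, 10% brisk movement, with mean bouts of ~20 s (`stay_prob = 0.95`).
  Free-living accelerometry is dominated by sedentary time and short bouts;
  a uniform state mix would also inflate every member's $\delta$ (most pairs
  would straddle states), washing out moderate anomalies.
* **Scenario effects** are deterministic transforms of the same random draws
  used for normal behavior, so `effect_scale = 0` reproduces the normal
  process *exactly* (the tests assert identity of the generated logs). The
  sprint and stairs scenarios add cadence (2.5–3 steps/s) with band-derived
  speed/distance following it, tenfold motion variance and a heart-rate ramp
  of 45–50 bpm; boxing adds fifteenfold motion variance plus spurious
  pedometer counts — a wrist-worn pedometer registers punches as steps, and
  the band derives speed and distance from the step stream; falls add sparse
  >3 g impact spikes with gyroscope transients, struggle-up motion and
  impact artifacts on the pedometer; breath holding suppresses steps and
  motion and applies a dip-then-rebound heart-rate excursion of ±35 bpm,
  the magnitude seen in maximal holds (diving-reflex bradycardia, rebound
  tachycardia).
* **Scales used in the tests.** One simulated hour per subject (~3600
  vectors) for the separation check; 1800-s logs with 300-s zero-effect
  scenario logs for the null calibration; smaller logs elsewhere. These are
  desk-scale choices — the generator happily produces days.

What the generator does *not* emulate: real sensor noise spectra, posture
transitions, heart-rate kinetics (it uses level shifts, not dynamics),
device dropout other than scheduled gaps, demographic heterogeneity beyond a
few profile knobs. Passing tests on this generator therefore show that the
pipeline detects *separable* deviations of the kind the scenarios encode and
is calibrated under the null — not that it reaches any particular accuracy
on real wearable data.

### Calibration properties and how they are asserted

With all effect sizes zero, anomaly logs are draws from the normal process,
so AUC should be 0.5. A single-run AUC on this kind of data is nevertheless
noisy, because activity states arrive in ~20-s blocks and a 300-s log
contains only a handful of exchangeable blocks; the per-seed spread is
roughly ±0.1 even for a perfectly calibrated detector. The null-calibration
test therefore asserts that each classifier's *mean* AUC over ten seeds lies
within 0.5 ± 0.05 — a bias check, which is what calibration means — rather
than demanding every individual seed land in that band. Detection strength is
separately asserted to be monotone in the effect scale (0, 0.5, 1) and above
0.95 at the default effects on a one-hour subject.

The breath-holding scenario is the informative edge case: it deviates only in
heart rate (a few tens of bpm) and in stillness, both numerically small next
to pace and speed, so it is the hardest scenario for raw-feature Euclidean
scoring — the rest-heavy mixing above is what keeps member thresholds small
enough for it to register at all. This mirrors the method's genuine
limitation rather than hiding it.

## Known limitations

* Euclidean distance on unscaled features means detectability is governed by
  a feature's numeric range, not its physiological importance.
* $\delta$ is a global scale per member; heteroscedastic normal behavior
  (tight rest cluster, diffuse activity cluster) makes rest-like anomalies
  intrinsically harder.
* Pooled-fold curves slightly favor methods whose score scale is stable
  across folds.
* The CLI's `evaluate` verb holds all subjects' feature tables in memory;
  week-long logs for dozens of subjects should be evaluated per subject.
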