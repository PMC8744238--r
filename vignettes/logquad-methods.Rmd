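---
title: "Modelling under-five age- and cause-specific mortality with logquad5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling under-five age- and cause-specific mortality with logquad5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logquad5)
library(dplyr)
```

## The problem

Cause-of-death estimates for children under five are usually available only
for broad age bands (neonates, infants, 1–59 months), while health
programmes increasingly target narrow age windows — a vaccine dose schedule,
for instance, needs mortality at specific months of life. The question this
package addresses is: given a population's under-five mortality
$_5q_0$ (all-cause or for one cause of death), and ideally its neonatal
mortality as well, what is the full age profile of cumulative mortality
across fine under-five age groups?

The quantity modelled throughout is the cumulative probability of dying
between birth and exact age $x$, written $_xq_0$, on the six-point age grid
0–6 and 0–27 completed days and 0–5, 0–11, 0–23 and 0–59 completed months.
The terminal cut point is the under-five bound, so $q$ at 60 months *is*
$_5q_0$. Cumulative probabilities are used rather than interval
probabilities $_nq_y$ because they are more stable, at the price of a hard
constraint: $_xq_0$ can never decrease with age.

## The model

For each age cut point $x$ and cause $c$, the package fits by ordinary
least squares the log quadratic relation

$$\log(_xq_{0,c}) = a_{x,c} + b_{x,c}\,\log(_5q_{0,c})
  + c_{x,c}\,\log(_5q_{0,c})^2 + v_{x,c}\,k,$$

with natural logarithms (the model is invariant to the base up to
rescaling of the coefficients). The first three terms describe the
*average* age pattern at a given level of under-five mortality. The rank-1
term $v_x k$ captures how individual life tables deviate systematically
from that average: $v$ — the *age deviation vector* — is the first right
singular vector of the matrix of OLS residuals (life tables × ages), and
$k$ is a per-life-table scalar. Two conventions pin down the otherwise
arbitrary scale split between $v$ and $k$: $v$ has unit Euclidean norm
over the included ages, and its entry at the youngest included age is
non-negative; the singular value is absorbed into $k$. This makes $k$
comparable across fits. The per-age residual standard deviation after
removing $v\,k$ is stored as `sigma` and drives the simulation study's
noise model.

At prediction time (`predict_pattern()`), $k = 0$ gives the average
pattern. When the target population's neonatal mortality is also known,
`calibrate_k()` solves the model exactly for the $k$ that reproduces it at
the anchor age (0–27 days by default):
$k = (\log q_\mathrm{anchor} - a - b L - c L^2)/v$ at the anchor, with
$L = \log{}_5q_0$. Anchored prediction therefore has *zero* error at the
anchor age, and every prediction has zero error at the terminal age, where
the schedule is pinned to the supplied $_5q_0$ — these two structural
zeros are asserted in the test suite and recomputed by the acceptance
script.

### Numerical choices and degenerate inputs

* **Zero cells.** For rare causes (injury in the first week, say) observed
  $_xq_{0,c}$ can legitimately be 0, where the log is undefined. Zero
  cells are excluded from that age's OLS, and records with any zero cell
  are excluded from the residual matrix for the SVD (complete-case). An
  optional positive floor (`q_floor`) substitutes for zeros instead, but
  is off by default: imputation would inject an arbitrary level into the
  fit.
* **Monotonicity repair.** Log-scale predictions can violate
  $_yq_0 \le {}_xq_0$ for $y < x$ when adjacent true probabilities are
  very close. `enforce_monotone()` works from the oldest age down, capping
  each younger value by the older one (`q[younger] <- min(q[younger],
  q[older])`); ties are allowed, repairs are recorded, and the operation
  is idempotent and never increases any entry. Prediction pins the
  terminal value to $_5q_0$ *before* repairing; since repair caps younger
  entries by older ones and never touches the terminal entry, this
  ordering guarantees monotonicity and exact terminal pinning
  simultaneously (the two properties would compete if pinning happened
  last and the pinned value fell below its neighbour).
* **Calibration guards.** A zero observed anchor probability (no neonatal
  deaths from the cause) falls back to $k = 0$ with a warning; a zero
  deviation entry at the anchor ($v_\mathrm{anchor} = 0$, as in a
  degenerate fit with no residual structure) raises a classed error
  instructing the same fallback, rather than silently dividing by zero.
* **Degenerate SVD.** If the residual matrix is numerically zero the
  deviation vector is set to 0 (not an arbitrary singular vector), `sigma`
  to 0, and calibration refuses.
* **q5 consistency.** On disk the under-five column is stored redundantly
  next to the terminal age column and cross-checked at 1e-9 (proportion
  scale), roughly float round-off for six-significant-digit inputs.
* **Day/month arithmetic.** The grid mixes day- and month-labelled cut
  points; a month is 30.4375 days unless configured otherwise on the
  `age_grid()`.

## The constant-hazard baseline

The comparator (`standard_predict()`) is what practitioners do when age
detail below five is unavailable: assume a constant mortality hazard
within 0–27 days and another within 1–59 months, calibrated to the
observed neonatal and under-five probabilities. The daily neonatal hazard
solves $1 - e^{-28\lambda_1} = q_\mathrm{neo}$; past 28 days — treated as
exactly one month at the splice — the monthly hazard solves
$(1-q_\mathrm{neo})e^{-m_T\lambda_2} = 1-{}_5q_0$ over the
$m_T = (1825-28)/30.4375 \approx 59$ months to the terminal cut point, so
both calibration identities hold exactly. A "constant mortality rate" is
read as a hazard statement, hence exponential interpolation; a
linear-in-$q$ variant is available (`interpolation = "linear"`) and
differs from it by less than 0.1 deaths per 1000 livebirths at realistic
magnitudes.

## Cross-validation

`loso_crossval()` mirrors the intended prediction setting: fit on all but
one stratum, then predict every held-out record three ways — average
pattern ($k=0$), anchored $k$ (using the held-out record's own observed
$_5q_0$ and anchor probability, which the prediction problem presumes
known), and the constant-hazard baseline calibrated to the same two
quantities. Errors are $|\hat q - q|$ (reported ×1000 as deaths per 1000
livebirths) and $|\hat q - q|/q$ (reported as %); relative-error cells
with observed $q = 0$ are excluded (the ratio is undefined) and counted.
Fold-level tables are retained and pooled by cell-count weighting — the
pooling identity is exact and tested — so an equal-fold-weight average can
be recomputed from the per-fold output if preferred.

## The simulation study

`run_sim_study()` asks how well the model is refitted and how well it
predicts when the truth is known. Each replicate draws `n_tables` life
tables (default 120, matching the 6-strata × 20-year shape of the
empirical design) from the fitted surface plus noise,

$$\log(_xq_{0,c}) = a + bL + cL^2 + v_x k + e_x,
  \qquad e_x \sim N(0, \sigma_x \cdot \mathrm{noise\_scale}),$$

with $_5q_{0,c} \sim U(2, 40)$ per 1000, $k \sim N(0,1)$ by default
(configurable to resample the training $k$'s — the generator's $k$ spread
is a genuinely open choice, as the unit-norm convention puts the empirical
spread partly in $k$ and partly in `sigma`), refits, and predicts
hypothetical held-out life tables at $_5q_{0,c}$ of 1, 2 and 3 per 1000
and at low/middle/high shape (default: the 25th/50th/75th percentiles of
the training $k$'s), anchored to the true neonatal value. Note the
scenario levels sit at or below the lower end of the training range; the
report flags such extrapolation. `sigma` is the *post-rank-1* residual
scale — the noise net of the systematic $v\,k$ term — which is the choice
consistent with $k$ appearing separately in the generating equation.

Randomness is controlled by one root seed; each replicate derives a
substream seed by a fixed affine counter (`substream_seed()`), so any
single replicate can be regenerated in isolation and identical
configurations reproduce byte-identical reports.

Two findings from this package's own test runs are worth recording as
caveats rather than claims:

* Prediction error behaves as expected — doubling `noise_scale` degrades
  mean absolute prediction error for a majority of age groups in every
  scenario (paired-seed comparison, 100 replicates).
* Individual *coefficients*, by contrast, are weakly identified at
  realistic collection sizes: over the simulated range of $_5q_0$ the
  design columns $\{1, L, L^2\}$ are nearly collinear, the $v\,k$ term
  adds large residual variance at young ages, and monotone repair
  truncates generated cells systematically downward. Mean absolute
  coefficient errors fall monotonically with `n_tables` (tested at 60,
  120, 480), but remain sizeable fractions of the smaller coefficients'
  magnitudes at n = 480. The fitted *surface* over the observed range —
  what prediction actually uses — is accurate; the raw coefficients
  should not be interpreted individually.

## The synthetic fixture generator

`make_mchss_like()` produces a sample-registration-style collection — six
geography × urbanicity strata over 1996–2015, an all-cause schedule plus
pneumonia-like and injury-like causes, 120 records per cause — entirely
from the log quadratic mechanism, returning both the observable set and
every latent draw ($k$, per-age noise, masked cells). Its coefficient
tables are constructed, not taken from any empirical source: the $k=0$
schedule is fixed as a fraction-of-$q_5$ profile at two anchor levels, a
small curvature is chosen, and $(a, b)$ are solved exactly through the
anchors; the terminal age is the identity $(0, 1, 0)$ with $v = 0$ and
$\sigma = 0$ by construction. Default levels were chosen once as
plausible for the setting emulated (all-cause $_5q_0$ declining from
roughly 14–62 to 5–20 per 1000 across strata over the period;
cause-specific levels an order of magnitude lower; log-scale noise of
0.03–0.08 for all-cause and 0.10–0.30 for the rarer causes, larger at
younger ages where counts are small; a few percent zero-inflation at the
youngest cause-specific ages to emulate observed 0.0 cells).

Zero-inflation masks a cell to zero *together with all younger cells* —
read as "no deaths observed up to that cut point" — because zeroing a
middle age alone would violate the cumulative-probability invariant.

What passing tests on this fixture do and do not show: the generator's
records satisfy the model family by construction, so results on it
demonstrate internal consistency (oracle equivalence, structural zeros,
error ordering among methods), not real-world accuracy. Real
surveillance data add age heaping, cause misclassification,
denominator error, and deviations from log-quadratic shape that the
fixture deliberately omits. Empirical error levels can only be
reproduced against the original surveillance data, which are an external
download and outside this package's test scope.

## Problem sizes used by the checks

The shipped tests and the acceptance script run at deliberately modest
sizes, chosen as the smallest that make each property unambiguous: OLS
and SVD oracles at 5–60 records; the pooling identity and structural
zeros on the 120-record fixture; noise-scale dominance at 100 paired
replicates; coefficient-consistency at 50 replicates × collection sizes
60/120/480; monotonicity over 10,000 randomized predictions; the
noise-injection check at a single 2000-table collection.

## Known limitations

* Causes are modelled as separate single-decrement schedules: no
  competing-risk correction and no reconciliation of cause-specific
  totals to the all-cause schedule (a pro-rata post-hoc scaling would be
  possible but is out of scope).
* Point predictions only; no uncertainty intervals.
* Mortality *rates* $_xm_0$ are not modelled, only cumulative
  probabilities.
* The stratum-wise hold-out is the only cross-validation design offered.
* Anchored prediction is exact at the anchor only when monotone repair
  leaves the anchor untouched; repairs there are recorded (and are rare
  except under extrapolation below the fitted range).
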