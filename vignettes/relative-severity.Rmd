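---
title: "Relative severity assessment: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative severity assessment: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relsev)
library(dplyr)
```

## The problem

Severity assessment in laboratory animals is traditionally done with
subjective clinical scorings. Quantitative outcome measures — body weight
change, burrowing performance, heart rate, heart rate variability,
temperature, activity — are objective, but each tells a different and
sometimes contradictory story: burrowing may collapse to zero while body
weight drops only a few percent, and heart rate rises while everything else
falls. `relsev` combines such multi-variable welfare time courses into a
single composite score per animal and time point, anchored to the maximal
deviations observed in a *reference cohort* whose qualitative severity is
known (e.g. a surgical transmitter-implantation cohort graded "moderate"
under the EU directive). The result is a *relative* severity scale: scores
are interpretable as fractions of the worst impairment the reference
procedure produced.

## The model

Three steps, all per animal:

1. **Baseline normalisation.** Each variable is rescaled so that the mean of
   its baseline phase (by convention all negative times; the intervention is
   at time 0) equals 100%. Values above 100% are kept — direction handling
   comes next.

2. **Directional weights.** Severity unfolds downward for most variables
   (weight, burrowing, activity, HRV) but upward for heart rate. For
   variable $i$ at time $t$ with normalised value $x_i(t)$, the deviation is
   $\delta_i(t) = \max(0,\, 100 - x_i(t))$ for decrease-type and
   $\max(0,\, x_i(t) - 100)$ for increase-type variables: deviations in the
   non-severity direction contribute zero. The weight is
   $$w_i(t) = \frac{\delta_i(t)}{\delta_i^{\max,\mathrm{ref}}},$$
   where $\delta_i^{\max,\mathrm{ref}}$ is the largest deviation of variable
   $i$ observed anywhere in the reference cohort (pooled over animals and
   post-baseline times). Weights are within-animal effect sizes on the
   reference scale; they may exceed 1 when a test animal is worse than
   anything in the reference.

3. **Composite score.** With $N(t)$ the number of *non-missing* weights at
   time $t$,
   $$\mathrm{RELSA}(t) = \sqrt{\frac{1}{N(t)} \sum_i w_i(t)^2}.$$
   The root mean square keeps the score on the scale of the individual
   weights and lets large deviations dominate small ones, which mostly carry
   noise. A score of 1 means all contributing variables simultaneously match
   the reference maxima; the per-animal maximum over time
   ($\mathrm{RELSA}_{\max}$) is the unit of between-animal and between-model
   comparison.

```{r workflow}
spec <- sim_spec(n_animals = 8, seed = 42)
cohort <- simulate_cohort(spec)
norm <- normalize_to_baseline(cohort, spec$variables)
ref <- build_reference_set(norm, spec$variables, label = "moderate")
fit <- relsa(cohort, ref)
glance(fit)
```

### Missing data and the meaning of $N$

Two situations must not be conflated. A variable *measured at baseline
level* contributes a weight of zero and counts toward $N$ — it is evidence
of absent severity and dilutes the score. A variable *not measured* at $t$
is excluded from both the sum and $N$ — the score is then the RMS of what
was actually observed. This is the only reading under which unmeasured
variables truly do not contribute; it also makes the score robust to
heterogeneous sampling (daily weighing against hourly telemetry): scoring
happens at the union of observed times, with absent variables simply left
out. If nothing is observed at $t$ the score is undefined (`NA`) and is
ignored by the per-animal maximum. No imputation is performed anywhere.

### Degenerate reference variables

A variable whose reference cohort never deviates in the severity direction
would have denominator zero. Dropping it silently would change the meaning
of $N$ for every later study, so `build_reference_set()` rejects the build
and names the variable — the caller must remove it explicitly.

## Severity levels

Per-animal maxima from several studies are clustered on the severity axis
to obtain ordered levels L1 < L2 < … < Lk, each with an upper threshold.

* **Clustering.** One-dimensional k-means. The default mode solves the
  problem *exactly* by dynamic programming (optimal 1-D clusters are
  contiguous in sorted order, so minimising within-cluster sum of squares is
  an optimal segmentation, $O(kn^2)$). A Lloyd mode with k-means++ seeding
  and 25 restarts is provided for continuity with common practice; on every
  desk-scale instance it attains the DP optimum, and when the optimum is
  unique it returns the identical partition. The DP mode is recommended for
  thresholds that will be published.
* **Choosing k.** The scree curve (WSS against k, computed exactly per k)
  is summarised by a deterministic elbow rule: the k maximising the second
  difference of **log** WSS over the candidate range (default 1–8). The log
  scale makes the rule scale-free; on raw WSS the second difference is
  always dominated by the first split whenever the curve decays
  geometrically, and would return k = 2 regardless of structure. The curve
  is returned so the choice can be inspected, and k can always be set
  explicitly.
* **Thresholds.** By default the largest observed value inside each sorted
  cluster, so a threshold reads "scores at or below this belong to this
  level or lower"; ties grade into the lower level. A midpoint mode
  (boundaries halfway between adjacent clusters) is available; the two
  coincide in how they order animals and differ only in where the no-man's
  land between clusters is cut. Values above the top threshold grade into
  the top level and are flagged `beyond_range`.

```{r levels}
mx <- relsa_max(fit)$relsa_max
lv <- cluster_relsa_max(c(mx, 0.12, 0.18, 0.45, 0.52), k = 3)
tidy(lv)
```

## Uncertainty

Group means of $\mathrm{RELSA}_{\max}$ and cluster centroids get 95%
bias-corrected and accelerated (BCa) bootstrap intervals (default
B = 10,000). The bias correction $z_0$ comes from the share of replicate
statistics below the point estimate and the acceleration $a$ from the
skewness of the jackknife distribution. Two degenerate regimes are handled
explicitly: with no resampling variability at all the interval collapses to
the point estimate; when only the jackknife variance is degenerate the BCa
adjustment is undefined and the function falls back to the plain percentile
interval with a warning (never silently). For centroid intervals, cluster
membership is held fixed and values are resampled within each cluster;
re-running the clustering inside every replicate is the main alternative,
but it makes replicate centroids exchange members across levels, so the
interval would no longer describe the stability of an identified level.
Singleton clusters cannot be resampled and carry `NA` bounds. Every
interval records B, the seed, $z_0$, $a$ and the method actually used.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the structure the method assumes:
a baseline plateau, a direction-aware deflection at the intervention
(time 0), exponential recovery with a per-variable half-life, additive
Gaussian noise expressed in percent points of baseline, per-variable
sampling periods, optional i.i.d. missingness on post-baseline
observations, and an optional humane-endpoint rule that truncates a series
when a variable's noiseless trajectory crosses a cut-off (e.g. 80% of
baseline weight). The default panel mimics a transmitter-implantation
cohort qualitatively — a ~11% body-weight drop with a 3-day half-life,
burrowing collapsing by ~74% and recovering within days, a transient heart
rate rise, an activity drop, and slowly recovering HRV — without claiming
to reproduce any real study's statistics. The exponential family was chosen
because the empirical recovery curves it stands in for are roughly monotone
with model-specific rates, which this family spans with one parameter.

What the generator deliberately does *not* emulate: correlated noise across
variables (real telemetry variables are collinear), circadian structure,
measurement-schedule irregularities beyond a fixed period, and informative
(severity-dependent) missingness. Tests that pass on simulated cohorts
therefore validate the *score algebra and pipeline plumbing*, not the
biological adequacy of any particular variable panel.

`engineer_known_severity()` inverts the score: it constructs a noise-free
animal whose weights all equal a prescribed target per time point (the RMS
of equal weights is that weight), giving an analytic ground truth — a
target of 1 reproduces the reference ceiling exactly.

## Numerical choices

* All score math is in double precision; package tests compare at 1e−9
  absolute, and oracle-equivalence checks against an independently coded
  brute-force evaluator at 1e−12.
* Baseline aggregation is the *mean* over the baseline window (default: all
  negative times). A multi-day window is robust to single-day noise and
  reduces to single-day normalisation when the window has one time point.
* Scale invariance: multiplying a raw variable by any positive constant
  cancels in the normalisation, leaving weights and scores unchanged.
* The radar-chart area fraction in `contribution_profile()` (polygon area at
  equal angles, relative to the all-ones polygon) depends on the variable
  order around the polygon and is advisory; the weight vectors themselves
  are the primitive output. With fewer than three variables the area is
  undefined.
* Validation problem sizes were chosen to exercise every code path at desk
  scale: 100 random cohorts for the oracle-equivalence suite, clustering
  fixtures up to 50 points (where exhaustive partition enumeration is still
  exact), and bootstrap calibration with 500 simulated normal samples of
  n = 30 at B = 2,000, which bounds the Monte-Carlo error on empirical
  coverage near one percentage point.

## Limitations

* The scale is *relative*: every statement inherits the qualitative
  severity judgment assigned to the reference cohort, and a reference with
  few animals or few post-baseline observations yields noisy maxima.
* Reference maxima are extremes and therefore sensitive to outliers in the
  reference cohort; no robustification (e.g. quantile-based maxima) is
  applied, matching the definition of the scale.
* Scores above 1 are meaningful ("worse than the reference ever got") but
  unbounded, so level thresholds derived from one set of studies need not
  transfer to others.
* The elbow rule is a deterministic surrogate for a visual judgment; for
  published level systems, inspect the scree curve and fix k explicitly.
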