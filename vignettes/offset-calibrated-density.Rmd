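---
title: "Offset-calibrated density estimation from community science counts"
author: "densitycal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offset-calibrated density estimation from community science counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densitycal)
```

## The problem

Opportunistic community science checklists (eBird-style records) carry
counts and effort metadata, but not the detection-process data — distances
and times of detection — needed to convert observed abundance into density
(birds per hectare) and hence into population size. Structured point counts
carry exactly that information. `densitycal` implements the bridge: fit
availability and perceptibility models to structured five-minute counts,
convert them into per-survey correction factors, and include those factors
as offsets in count models built on community checklists. Because no real
structured or community dataset ships with the package, a fully seeded
synthetic-data module generates landscapes, bird populations, and both
survey types with the statistical structure the estimators assume, so every
claim the package makes is checked end to end against a known truth.

## The detection model and offsets

Imperfect detection on a point count factors into two components.

**Availability.** A bird present at the survey gives its first detectable
cue at an exponential time with rate $\varphi$ (cues per minute). Over a
count of duration $T$ the availability probability is
$p = 1 - e^{-\varphi T}$. The structured surveys record, for each detected
individual, the first one-minute interval of detection (the *removal*
interval). Conditional on detection within $T$, the interval $j$ follows a
multinomial with cell probabilities

$$\pi_j(\varphi) = \frac{e^{-\varphi t_{j-1}} - e^{-\varphi t_j}}
                        {1 - e^{-\varphi t_J}},$$

which is the likelihood `fit_removal_set()` maximizes, with
$\log \varphi$ linear in scaled Julian day and time of day (candidate set:
all combinations of the two covariates with optional quadratics, plus the
null — nine models, ranked by AICc).

**Perceptibility.** An available bird at distance $r$ is perceived with
half-normal probability $g(r) = e^{-r^2/\tau^2}$. Structured surveys record
distances in 50-m bands up to 200 m with an unbounded last band. For a
(locally) uniform bird density the detected distances have density
proportional to $2\pi r\, g(r)$, so band $k$ has probability
$\pi_k(\tau) = e^{-r_{k-1}^2/\tau^2} - e^{-r_k^2/\tau^2}$
(`distance_cell_probs()`). Because the last band is unbounded, density over
the sampled area is not directly estimable; instead we use the *effective
detection radius* $\rho$, defined by the balance
$\int_0^{\rho} (1-g)\,2\pi r\,dr = \int_{\rho}^{\infty} g\,2\pi r\,dr$.
For the half-normal, $\rho = \tau$ exactly; `edr_from_integral()` exposes
the defining integral so tests can verify the identity numerically.
`fit_distance_set()` models $\log \tau$ in two AICc stages: noise
covariates first (distance to river and highway, in linear, quadratic, and
log forms, singly and in combination), then vegetation and urban covers
added to the winning noise structure.

**Offsets.** The expected count at a survey is $E[Y] = D \cdot C$ with
$C = A\,p\,q$: effective area $A = \pi\rho^2$ (hectares), availability $p$
at the checklist's *actual* duration, and perceptibility $q = 1$ by
definition within the effective area. `compute_offsets()` evaluates $C$
per survey; $\log C$ enters the Poisson count stage as an offset, so the
fitted surface is density itself.

Only the half-normal key function is implemented: the estimators and the
EDR are then closed-form, and the simulator generates exactly this
detection process, so the model is correctly specified for the synthetic
data by construction. Hazard-rate and uniform keys are out of scope.

## The zero-inflated density pipeline

Each framework runs the same three-stage pipeline per iteration:

1. **Occurrence stage.** A probability-of-occurrence learner is trained on
   detection/non-detection with all focal covariates at all five radii
   (75, 165, 315, 615, 1215 m), and evaluated by AUC on the independent
   structured test set.
2. **Prevalence threshold.** The training-set prevalence is the cutoff
   converting continuous predictions into a binary suitability mask (ties
   count as suitable; the source method leaves the tie direction
   unspecified). Suitable area is the suitable-cell count times cell area.
3. **Count stage.** Surveys inside the mask, with their offsets, train a
   Poisson learner; density is predicted for every suitable cell, giving
   mean density over suitable cells and population
   $\hat{N} = \sum_{\text{suitable}} \hat{D}_c \times \text{cell area}$.
   Predictive performance is the Pearson correlation between
   $\hat{D}(\text{site}) \times C_{\text{test}}$ and observed test counts.

"Mean density" is defined over suitable cells (not the whole study area);
the source method does not pin this down, and the suitable-cell mean is the
quantity its population estimate implies.

**Learners.** The learner abstraction specifies loss, interaction depth 3,
bag fraction 0.75, and 10-fold seeded cross-validation choosing the
ensemble size, with the learning rate halved until the optimum falls in
[1000, 5000] trees. Two implementations are provided: a boosted-tree
ensemble (xgboost, with the exposure entering as `base_margin` and a
neutral `base_score` so the offset is the only exposure term), and a
deterministic penalized log-linear fallback (glmnet ridge with seeded
cross-validated penalty; the intercept and the offset are unpenalized, so
the exposure contract — doubling all offsets exactly halves fitted
density — holds to numerical precision). The fallback is first-class and is
the default in tests: it is fast, deterministic, and correctly specified
for the synthetic truth, which is log-linear.

## Frameworks

* **Benchmark** — the structured data end to end: a benchmark subset the
  size of the community dataset (sampled without replacement; the remainder
  is the shared independent test set), detection models from its own
  removal/distance records, counts from its own 5-min surveys.
* **Fixed** — community data only, with every offset equal to
  $\pi \times 200^2\,\mathrm{m}^2 \approx 12.57$ ha and $p = q = 1$. This
  is the perfect-detection assumption; with a true scale $\tau$ and true
  availability $p$, its population estimate is biased by roughly
  $\tau^2 p / 200^2$.
* **Independent** — community data for both model stages; detection models
  from the complete structured dataset restricted to the iteration's
  suitable mask. Detection models are refit per iteration (the mask
  changes across iterations in general); the source method does not state
  whether it refit, and per-iteration refit keeps the stage order
  symmetric across frameworks.
* **Calibration** — detection models from a small calibration subset
  resampled per iteration from the benchmark set until it contains
  `n_occ` surveys with at least one detection (10/30/100/250), negatives
  drawn en route included. With pooling, the calibration surveys (with
  their own offsets) join the community data in the occurrence *and*
  count stages.

Endpoints (AUC, suitable area, mean density, population) are converted to
percent of the benchmark's per-endpoint median across iterations
(`compare()`), with medians reported throughout.

## The synthetic-data module

`generate_landscape()` builds standardized, spatially autocorrelated
covariate layers (white noise convolved with a Gaussian kernel) on a
half-open square grid, with focal means at the five radii computed by
averaging cells whose centers fall within the radius (edge windows are
renormalized). `species_truth()` defines logistic suitability thresholded
to a truly suitable cell set, log-linear density inside it, and log-linear
$\varphi$ and $\tau$ surfaces. Birds are realized as an inhomogeneous
Poisson point process; structured surveys apply the exact detection
mechanism the estimators assume (exponential first cue; one Bernoulli
half-normal perceptibility trial per bird — per bird, not per cue, which is
the simplest mechanism consistent with a half-normal distance function).
Community checklists add hotspot-clustered locations, variable duration
(uniform on 3–30 min), protocol and location-type labels, incomplete
lists, pre-dawn and late start times, and observer profiles: a
detection-scale multiplier $\kappa$ on $\tau$ (community observers who
perceive a species at shorter range), binomial count thinning, and
presence-only "X" substitution. Dates are Julian day 120–190 and start
times −60 to 480 minutes from nautical dawn, so the seven-hour filtering
window has something to remove.

Fixture scenarios pin the study conditions. All use a 48 × 48 grid of
100-m cells, 500 structured surveys, 1500 raw community checklists,
$\tau = 80$ m, and a cue rate giving availability 0.8 on a 5-min count.
The suitable fraction of the landscape is fixed at scenario build time by
anchoring the suitability intercept at the realized covariate quantile
(0.45 for common/uncommon scenarios, 0.10 for rare), so each scenario's
rarity class holds for every seed. Density intercepts are 1.3, 0.4, and
0.35 birds/ha for common, uncommon, and rare; `aurally_cryptic` sets
community $\kappa = 0.6$; `homogeneous` removes the density covariate for
mechanism checks. These values were chosen by simulation during fixture
construction so the scenarios land in the intended prevalence classes
(common structured prevalence near 0.4; rare with too few positives to
support large calibration datasets).

What the simulator does *not* emulate: real spatial misregistration
between checklist locations and habitat, temporal population trends,
multi-observer parties, double counting, species misidentification, or
count heaping. Passing tests therefore demonstrate that the estimators
invert the detection process they assume, not that real community data
satisfy those assumptions.

## Numerical choices

* **Optimizer.** Detection models are fit by BFGS on unconstrained
  coefficients. The scale intercept is initialized at the log RMS of the
  observed band midpoints (removal: $\log(2/T)$), not at zero: at zero the
  implied $\tau = 1$ m collapses all mass into the first band, later-band
  probabilities underflow, and the numeric gradient vanishes. Failed fits
  are retried from three seeded jittered starts.
* **Prediction clamps.** Predicted $\varphi$ is clamped to
  $[10^{-4}, 100]$ per minute and $\tau$ to $[1, 5000]$ m so sparse fits
  cannot overflow downstream offsets.
* **Sparse-data guard.** Covariate candidates enter the AICc competition
  only with at least 15 individuals per non-intercept parameter (the null
  always fits); with a couple dozen individuals, flexible candidates
  otherwise win by saturation and produce degenerate offsets. The hard
  floor `n > k + 1` (AICc's own requirement) is separate.
* **Degenerate cases.** If the mask-restricted detection surveys carry
  fewer than 20 individual detections, the full survey set is used with a
  warning (detection probability is not suitability-dependent). All-zero
  count training data yield a zero density surface rather than a divergent
  fit. Undefined results (zero-variance predictive correlation, zero
  benchmark medians) signal a classed warning and return `NA`, never a
  silent `NaN`.
* **Conventions.** Cells are half-open with the origin at the landscape
  corner (a point on a boundary belongs to the upper/right cell); the
  200-m sampling grid is anchored at the same origin (the source method
  does not state its grid convention). Areas are hectares, densities
  birds/ha, distances meters, durations minutes. AICc uses the number of
  individuals as $n$. Even-length medians use the midpoint rule. All
  randomness flows from a master seed through `child_seeds()`.

## Problem sizes in the test suite

The suite runs the full analysis at desk scale with the fallback learner:
detection-model recovery at 2000 individuals (selection consistency at
4000), offset unbiasedness at 500 surveys, and framework endpoints on the
fixture scenarios with up to ten seeds and ten iterations per run. These
sizes were chosen so that Monte-Carlo error is small relative to the
tolerances being checked while the whole suite stays comfortably
desk-sized.

## Known limitations

* Half-normal perceptibility only; no hazard-rate key, no time-varying
  cue rates within a count, no finite-mixture availability.
* The occurrence and count stages share no information (two-stage, not a
  joint zero-inflated likelihood).
* The prevalence threshold is a heuristic: when detectability within
  suitable habitat is well below 1, the implied mask can be conservative;
  the synthetic scenarios are built so the threshold sits near the
  occurrence-probability midpoint, which real species need not obey.
* Percent-of-benchmark comparisons inherit the benchmark's own sampling
  noise, especially for rare species where few positive surveys exist.
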