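---
title: "Modelling spatially heterogeneous lek responses to energy development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatially heterogeneous lek responses to energy development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lekscape)
```

## The problem

Male greater sage-grouse gather each spring at traditional display sites
(leks); the peak count of displaying males indexes the local breeding
population.  Oil and gas well pads are the dominant disturbance unit on
sagebrush landscapes, and the central questions this package addresses are
*where*, at *what spatial scale* (window radius around a lek), and after
*what time lag* pad density depresses male lek attendance — allowing for
the possibility that the response differs from region to region rather
than being a single statewide coefficient.

The pipeline has five stages, each usable on its own:

1. **Eligibility filtering** — leks must be surveyed in all of the last 3
   years, at least 4 of the last 5, and at least 6 of the last 10
   including the first window year, so that 3-, 5- and 10-year trend
   regressions are all supportable.
2. **Density covariates** — roving-window point density of *active* pads
   (pads/km²) within 0.5, 1, 2, 5 and 10 km of each lek, evaluated 1, 3,
   5 and 10 years before the trend window starts.
3. **Trend responses** — LOWESS detrending of each lek's count series
   (lek counts cycle over 3–5 year periods), then ordinary least-squares
   slopes of the adjusted counts over the most recent 3, 5 and 10 years,
   plus the adjusted final-year count and a binary increasing/decreasing
   flag.
4. **Geographically weighted regression (GWR)** — local coefficients of
   trend on lagged density, bandwidth selection by corrected AIC, local
   t-tests, an F comparison against the global model, and Monte Carlo
   permutation tests of coefficient nonstationarity.
5. **Mapping and thresholds** — inverse distance weighted surfaces of the
   significant local responses, regional summaries, and functional
   response lines inverted into sustainable-density thresholds.

## Trend detrending

Lek-count series show multi-year periodicity: over 3–5 year windows a lek
can appear to flip between increase and decline even when its decade-scale
trajectory is stable.  Fitting a trend to raw short windows would conflate
that cycle with the development response, so counts are first smoothed.

The smoother is local linear regression (LOWESS) with tricube weights over
the `ceiling(span * n)` nearest years.  The span is chosen from the
candidate grid {0.3, 0.4, …, 1.0} by the corrected AIC
$$AIC_c = n\log(RSS/n) + \frac{2kn}{n-k-1}, \qquad k = \operatorname{tr}(S),$$
where $S$ is the explicit smoother matrix; ties break toward the smaller
span for reproducibility, and spans whose effective parameters exhaust the
residual degrees of freedom are treated as unusable.  Building $S$
explicitly (rather than using a library smoother) is what makes
$\operatorname{tr}(S)$, predictions at unsurveyed years, and the exactness
guarantees below possible.

**Fitting scale.**  The smoother is fit on the *count* scale by default,
with the result bounded to $[0, c_{max}+1)$.  An alternative fits on the
empirical-logit scale ($p = (c+0.5)/(c_{max}+1)$, the offset keeping the
logit finite at zero and at the maximum) and back-transforms
(`lowess_scale = "logit"`).  The count scale is the default because a
local *linear* smoother reproduces any exactly linear count series for
every span, so the full stack — smoothing followed by windowed
regression — recovers linear trends to machine precision; on the logit
scale the transform bends linear series and any non-interpolating smoother
then biases the slope.  That exactness is the property the validation
suite leans on, and in our judgement the right default for a trend
estimator.  The logit path remains available when hard range-bounding
through the link is preferred.

Unsurveyed years inside the window are filled by evaluating the smooth
there, not by imputing raw counts: the windowed regressions are defined on
the smoother's predictions, which exist for every year.  A
surveyed-but-inactive lek is an observed zero.  An all-zero series smooths
to zeros.  A trend slope of exactly zero maps to "not increasing" (binary
0); the tie is documented rather than randomised.

## The GWR engine

For response $y_i$ (one trend kind per fit) with covariate row $x_i$
(intercept plus selected lagged densities) at planar coordinates $u_i$,
the local model is $y_i = x_i'\beta(u_i) + \varepsilon_i$, estimated at
each lek by weighted least squares,
$\hat\beta(u_i) = (X'W_iX)^{-1}X'W_iy$, with kernel weights centred on
lek $i$.

* **Kernel.**  Default adaptive bisquare, $w = (1-(d/b)^2)^2$ for
  $d < b$, with $b$ the distance to the $k$-th nearest neighbour: leks
  cluster regionally, and an adaptive kernel keeps the effective local
  sample size stable where leks are sparse.  A fixed-bandwidth gaussian
  kernel is available; it is what the global-limit identities use
  (weights never vanish, so the fit degenerates smoothly to global OLS as
  the bandwidth grows).
* **Bandwidth.**  Golden-section search minimising the GWR corrected AIC
  $$AIC_c = n\log(RSS/n) + n\log(2\pi) +
    n\,\frac{n + \operatorname{tr}(S)}{n - 2 - \operatorname{tr}(S)}$$
  over $[p+2, n]$ neighbours (adaptive) or [minimum pairwise distance,
  extent diagonal] (fixed).  The search is deterministic; a coarse grid
  scan guards against non-unimodal profiles (grid optimum returned with a
  warning when it beats the golden section).
* **Inference.**  Local standard errors use the model-level error
  variance $\hat\sigma^2 = RSS/(n - ep)$ with effective parameters
  $ep = 2\operatorname{tr}(S) - \operatorname{tr}(S'S)$; both
  $\operatorname{tr}(S)$ and $ep$ are reported, since published "number
  of parameters" figures do not always say which was meant.  Local
  t-values use $n - ep$ degrees of freedom.  We emit t-values (not
  z-scores) and note that usage varies in the applied literature.
* **Model comparison.**  $F = \frac{(RSS_{global}-RSS_{gwr})/(ep-p)}
  {RSS_{gwr}/(n-ep)}$ against the global OLS fit, with approximate F
  degrees of freedom; undefined (reported as such) when $ep \le p$.
* **Pseudo-R².**  $1 - RSS/TSS$ (gaussian) or a deviance ratio
  (binomial).  These are *not* bounded by 0–1 and are not comparable
  across responses with different magnitudes or variance structure; every
  fit carries that caveat in its `notes` field.
* **Binomial family.**  Geographically weighted logistic regression via
  local iteratively reweighted least squares (max 25 iterations,
  tolerance 1e-8); non-convergent leks are flagged.  Rank-deficient local
  fits are flagged and excluded from maps without aborting the run.

### Monte Carlo nonstationarity test

The observed statistic per covariate is the variance of its local
coefficients across leks.  Each of $B$ permutations shuffles the
coordinate rows against the fixed $(y, X)$ rows and refits with the *same*
bandwidth; $p = (1 + \#\{perm \ge obs\})/(1+B)$.  Holding the bandwidth
fixed keeps the permutations exchangeable with the observed arrangement
(and is computationally necessary); re-selecting per permutation is
possible in principle but not offered.  Variances at machine-precision
zero are clamped to exact zero so the degenerate global limit gives
$p = 1$.  With locations exchangeable under the null the test is exact:
at $B = 99$, $P(p \le 0.05) = 0.05$.

## Density conventions

Density is the literal closed-disc count over area: pads with
$d \le r$ count, divided by $\pi r^2$ with no edge correction —
standard GIS point-density semantics.  A pad is active in year $t$ when
it was actually drilled by $t$ (permit-only records, class `"AP"` or a
missing start year, never count) and activity has not ceased before $t$.
Lags are first-class configuration: the covariate for lag $\ell$ is the
density in year `window_start - ` $\ell$.  `count_to_density()` /
`density_to_count()` expose the conversion explicitly because published
threshold statements sometimes equate densities with pad counts under
unstated conventions (0.7 pads/km² within 10 km is ~220 pads under the
literal conversion, not 7); this package implements the literal
definition and leaves any alternative reading to the caller.

## The synthetic landscape generator

`generate_leks()`, `generate_wellpads()` and `generate_counts()` produce
data with *known* spatially varying lagged responses:

* leks uniform over a rectangular extent;
* pads activated with Poisson counts whose intensity grows geometrically
  (`growth = 1.066` over 20 years ≈ the 3.6-fold intensification observed
  on these landscapes), placed uniformly or as a Thomas cluster process
  (the dispersed-versus-clustered development contrast);
* expected counts
  $m(i,t) = \max\{0,\, b_i + \sum_k \beta_k(u_i) D_k(i, t-\ell_k)(t-t_0)
  + A\sin(2\pi t/P)\}$, observed either exactly (noiseless) or as
  Poisson draws.

Zero-truncation (not a log link) keeps the linear trend responses exactly
recoverable in the noiseless limit, which is what makes closed-form
validation possible.  Periodicity is a single sinusoid because only the
existence of a 3–5 year cycle is established, not its shape; amplitude
and period are free configuration (defaults: amplitude 0 in the
generator's truth object — enable explicitly, e.g. $A=3$, $P=6$ y, a
plausible magnitude for mid-sized leks).  What the generator does *not*
emulate: demographic mechanisms (recruitment, survival, philopatry — the
lag is imposed phenomenologically, as in the regression design),
observation error in lek finding, surveyor effects, weather covariates,
or habitat heterogeneity.  Passing recovery tests on this generator shows
the *estimator* is correct, not that real lek dynamics satisfy the model.

## Validation design and problem sizes

The test suite validates every stage against independent oracles: naive
all-pairs counting for densities, `stats::lm` weighted fits for the local
solves, unit-vector reconstruction of the smoother matrix for the AICc
span search.  The headline recovery benchmark uses 400 leks on a
100 × 100 km extent with a step coefficient field (−4 males/lek/year per
pad/km² in the west half, 0 in the east): the engine must recover the
sign at ≥90% of leks away from the step and keep the mean absolute
coefficient error under 25% of the step height.  Permutation-test
calibration uses 500 stationary replicates of 50 leks (99 permutations
each) and requires the empirical type-I rate at nominal 0.05 to fall in
[0.02, 0.10]; power is assessed on 100 noiseless step-field replicates of
100 leks, where the heterogeneity signal should be detected at least 80%
of the time.  These sizes give the calibration checks adequate binomial
precision (±0.01 SE on the type-I rate) while each replicate remains a
sub-second fit.

## Numerical choices and degenerate inputs

* Tricube neighbourhood scale inflated by 5% so the furthest neighbour
  keeps a small positive weight and weighted designs stay full rank; the
  minimum neighbourhood is 3 points.
* `RSS` is floored at 1e-300 inside logs; effective-parameter
  denominators are guarded (`n-k-1 <= 0` → span unusable,
  `n-2-tr(S) <= 0` → AICc infinite).
* Distance ties at exactly the window radius are *included* (closed
  disc) — deterministic and consistent with count/area semantics.
* IDW cells coinciding with a sample point take the sample value exactly;
  all other cells are convex combinations, so surfaces never leave the
  sample range.  Power defaults to 2, the conventional GIS default.
* Opposing-response pairing is greedy and deterministic (increasing leks
  in id order, nearest-density unused decreasing lek, 5% relative
  tolerance), since published counts of such pairs never state a matching
  rule; each lek appears in at most one pair.
* Per-lek significance maps use uncorrected local t-tests by default,
  matching field practice for GWR maps; a Benjamini–Hochberg option
  exists and is stricter.

## Known limitations

* Coordinates are assumed already projected; no geodesy or reprojection.
* No detection-probability correction: counts are treated as censuses of
  displaying males, so all trends are trends in *counted* attendance.
* The forecast aggregator is an unweighted mean over response lines; the
  per-line vector is always returned because any single-number statewide
  forecast depends on an aggregation convention.
* Pseudo-R² comparisons across response kinds are intentionally
  inconvenient (the caveat travels with every fit object): they are only
  meaningful between models of the same response on the same data.
* The Monte Carlo test fixes the bandwidth at the observed-data optimum;
  a bandwidth re-selected under permutation would be slightly more
  conservative.
* The generative model's zero-truncation introduces a real nonlinearity:
  when simulated development is intense enough to drive expected counts to
  the floor, the trend–density relationship saturates and locally fitted
  slopes can flatten or even invert.  Linear response lines (and linear
  GWR) are only faithful below that regime — which is equally true of the
  field data such models are fit to.
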