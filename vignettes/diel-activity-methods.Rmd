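---
title: "Methods: diel activity analysis of camera-trap communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel activity analysis of camera-trap communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`camtrapdiel` analyses how ground-dwelling and scansorial tropical forest
mammals distribute their activity over the 24 h day, from raw camera-trap
photo tables to three complementary analyses: (i) multinomial models of the
probability of day, twilight and night activity as a function of body mass
and trophic guild, (ii) Poisson mixed models testing whether one group's
hourly activity tracks (bottom-up) or avoids (top-down) another's, and
(iii) pairwise coefficients of activity overlap with bootstrap uncertainty.
This vignette is the package's account of the methods, their assumptions,
and the design decisions taken where the methodology was genuinely open.

## Solar geometry and the sun-anchored clock

Day length varies across sites and seasons, so clock time is not comparable
between an equatorial and a subtropical camera. Two devices remove this:

* **Diel classification.** Sunrise/sunset are computed at solar altitude
  -0.833° (refraction plus solar radius) and nautical dawn/dusk at -12°,
  from standard NOAA almanac formulas (Julian-century solar position,
  equation of time, hour-angle inversion, one refinement pass). *Day* is
  `[sunrise, sunset)`; *twilight* is `[nautical dawn, sunrise)` union
  `[sunset, nautical dusk)`; *night* is the rest. Intervals are half-open
  and left-closed so the three categories tile the civil day exactly. The
  morning twilight boundary is read as **nautical** dawn, for symmetry with
  nautical dusk: the night interval ends at nautical dawn, so any other
  dawn definition would leave a gap in the partition.
* **Double anchoring.** Each event time is mapped to a circle on which
  sunrise is always π/2 and sunset always 3π/2, by linear interpolation
  within the day arc and within the night arc; π is solar noon and 0 solar
  midnight regardless of photoperiod. The transform is continuous and, for
  a fixed site and date, invertible (`sun_anchor_invert()`); tests verify
  the round trip to under one second and agreement with an independently
  implemented Michalsky-type almanac oracle to within ±2 minutes over a
  latitude x season grid.

Timestamps are interpreted as site-local standard time with the zone offset
derived from longitude (`round(lon/15)` hours); polar dates where a sun
event does not exist return an explicit missing value and downstream
functions refuse to classify rather than defaulting silently. Atmospheric
corrections beyond the fixed -0.833° are out of scope.

## From photos to independent events

Camera traps photograph the same visit repeatedly. The filter chain is:

1. keep species with body mass **> 75 g** and ground/scansorial strata
   (smaller and arboreal species are unreliably detected);
2. collapse bursts into **independent events**: a detection is kept iff its
   gap to the last *retained* event of that species at that camera exceeds
   1 h. Measuring the gap to the last retained event (rather than the last
   raw photo) guarantees retained events are pairwise > 1 h apart and makes
   the filter idempotent; the alternative convention is available via
   `rule = "last_photo"`;
3. classify each event's diel category and anchored time; `anchored_hour`
   is `floor(24 * theta / 2π)`, i.e. 24 equal arcs of the anchored circle.

Guilds follow fractional diet at an inclusive 80% threshold (carnivore
≥ 0.80 vertebrates, herbivore ≥ 0.80 plants, insectivore ≥ 0.80
invertebrates, otherwise omnivore). Size classes split at 20 kg; species
above 580 kg face negligible predation and are excluded from the coupling
analysis only. A ≥ 25-event minimum applies to density plots and overlap
estimates, not to model fitting.

## Multinomial diel model with area random intercepts

For event *i* in protected area *a*, with day as the reference category:

$$\log\frac{p_{night}}{p_{day}} = x_i^\top\beta_n + b_{n,a}, \qquad
  \log\frac{p_{twilight}}{p_{day}} = x_i^\top\beta_t + b_{t,a},$$

with independent Gaussian intercepts $b_{n,a} \sim N(0, \sigma_n^2)$,
$b_{t,a} \sim N(0, \sigma_t^2)$ per area and non-reference category.
Covariates are trophic guild, the natural log of body mass in grams, and
their interaction; the candidate set is the nested quintet {1, mass, guild,
mass + guild, mass x guild}, ranked by AIC with ΔAIC < 2 treated as equal
support. Day as reference makes "nocturnality" a single coefficient
direction.

**Estimation.** The marginal likelihood integrates the intercepts out by a
Laplace approximation. Because the integrand factorises over areas, each
area contributes a two-dimensional conditional mode, found by damped Newton
iteration (the conditional log-posterior is strictly concave, so the
iteration is safe); the outer optimisation over the fixed effects and the
two log-SDs uses `nlminb` with an **exact analytic gradient** — the
envelope term plus the log-determinant correction, which requires the third
derivatives of the multinomial log-likelihood and the implicit response of
the modes. The design matrix is centred and scaled internally for
conditioning and the coefficients mapped back. Events are aggregated to
multinomial cells (unique covariate row x area) first, so cost is
independent of the number of events. The convergence tolerance defaults to
1e-6. Standard errors come from the numerically differentiated Hessian of
the Laplace objective at the optimum.

**ML, not REML.** There is no standard REML analogue for a multinomial
mixed model, so final estimates are plain Laplace ML and the fitted
object's `stage` field records `"ML"` to make that explicit.

**Degenerate inputs.** An entirely empty category is an error naming the
category; quasi-separation (a sparse guild x category cell fit perfectly by
a diverging coefficient) is an error, and `fit_candidate_set()` drops such
candidates from the ranking with a warning — the usual treatment of
non-converging models. A single protected area cannot identify the random
intercept and falls back to a fixed-effects multinomial fit with a warning.

**Prediction.** Probabilities use the fixed effects at the random-effect
mode 0 through an overflow-safe softmax; 95% intervals come from 1000
draws of the coefficient vector from its asymptotic normal distribution
(the delta method degrades near probabilities of 0 or 1). Masses outside
the fitted range are permitted but flagged `extrapolated`.
`nocturnality_ratio()` reports a ratio of two night probabilities rounded
to one decimal, the convention used for headline comparisons.

## Hourly coupling GLMM

Bottom-up versus top-down influence is tested by regressing one group's
sun-anchored hourly counts (24 bins per protected area) on another's with
`log E[response] = α + β · predictor + b_area`, Poisson errors, and a
Gaussian area intercept, restricted to areas where large carnivores were
detected. A Wald 95% CI above zero is read as bottom-up coupling, below
zero as top-down avoidance. Decisions taken where the method was open:

* the predictor enters as the **raw hourly count** (the effect is per
  event); a standardised predictor is available via `scale_predictor`;
* **Wald** rather than profile intervals — immaterial at these counts;
* **no effort offset** by default, since a standardised protocol equalises
  effort across bins within an area; a per-row log-effort offset is
  available;
* counts are aggregated over the whole deployment within an area (one
  model per comparison, area random intercepts only).

Pairs with fewer than 25 events in either group, and models that do not
converge, are reported as skipped rather than estimated.

## Circular densities and overlap

Activity densities are von Mises kernel density estimates on the anchored
circle. The kernel concentration uses the Taylor plug-in rule
$\kappa_{bw} = \left(\frac{3 n \hat\kappa^2 I_2(2\hat\kappa)}
{4\sqrt{\pi} I_1(\hat\kappa)^2}\right)^{2/5}$ with $\hat\kappa$ the ML von
Mises concentration of the sample; `adjust` divides $\kappa_{bw}$ (larger
values smooth more). Estimation uses a 128-point grid (512 for plots);
densities are renormalised so the circular trapezoid integral is 1 ± 1e-6.

Two overlap estimators are provided: Dhat1 integrates `min(f, g)` on the
shared grid; Dhat4 averages the capped density ratios at the sample points
(densities floored at 1e-12 with a warning). The dispatch rule — **Dhat1
when the smaller group has < 75 events, Dhat4 otherwise** — follows the
estimator literature's small/large-sample recommendation; the convention
is exposed so either can be forced. Bandwidth adjustments default to 0.8
(Dhat1) and 1.0 (Dhat4).

Uncertainty comes from a **smoothed bootstrap** (resample the data, add von
Mises kernel noise at the fitted concentration; 500 iterations), with the
percentile interval shifted so the bootstrap mean matches the point
estimate, clamped to [0, 1]; naive resampling would rediscover the same
atoms and understate variance at these sample sizes. The null probability
`p_null` draws both groups, at their observed sizes, from the KDE fitted to
the pooled sample and reports the proportion of null overlaps at or below
the observed one — a one-sided (low-overlap, i.e. avoidance) test, the
reading consistent with interpreting small values as temporal avoidance.
Overlap is never pooled across protected areas: pooling heterogeneous
schedules inflates the coefficient.

## The synthetic generator

The generator emulates a standardised multi-area tropical survey: several
protected areas within ±30° latitude, 60-90 cameras per area active for
~30 consecutive days, a community of > 75 g species, Poisson visits per
camera-day, and photo bursts with exponential 2-minute gaps so the
independence filter has realistic work. Ground truth is a three-category
multinomial logit with day as reference:
$\eta_{night} = a_g + s_g \log_{10}(\text{mass})$ per guild and a constant
twilight log-odds. This parameterisation (rather than specifying the
nocturnal weight directly as an inverse logit) was chosen so that
`log(p_night/p_day)` is *exactly* linear in log mass — the downstream
multinomial model is then correctly specified and slope recovery has an
unambiguous truth. Given its category, an event's anchored time is drawn
from the matching von Mises component (nocturnal centred 0, diurnal centred
π) truncated to that category's band for the site and date; twilight times
are uniform on their narrow arcs, where the component shape is irrelevant.
The realised category therefore always matches the downstream
classification, and empirical category frequencies converge to the
ground-truth probabilities.

Default study conditions: 4 areas between 20°S and 20°N, 60 cameras/area,
30 days, 20 species, masses log-uniform on 100 g-200 kg, guild mix 40%
herbivore / 20% carnivore / 20% insectivore / 20% omnivore, night/day
log-odds slopes per log10 mass of +0.8 (herbivore), +0.6 (insectivore),
-0.8 (carnivore), -0.5 (omnivore) — signs matching the cross-regional
pattern the analyses are designed to detect — intercepts centring the odds
at 10 kg, constant twilight log-odds of -2.5 (about 5-8% twilight events),
von Mises concentration 1.5, 0.3 visits per camera-day, and area intercept
SDs of 0.3 (night) and 0.2 (twilight). Per-species detection rates are not
dictated by any survey standard, so relative rates are Gamma(2) draws
normalised to 1.

For interaction scenarios, predator counts per anchored hour follow a
smooth night-peaked baseline `exp(0.7 + 0.8 cos θ)` and prey counts are
Poisson with `log`-mean `α_site + β · predator`, `α_site ~ N(0.3, 0.4²)`;
the sign of `β` must match the declared scenario. `simulate_diel_counts()`
draws event-level categories directly from the ground truth with Gaussian
area intercepts — the generator used by the model-recovery studies, while
the full detection stream exercises the solar and event stages.

**What the generator does not emulate:** imperfect or distance-dependent
detection, species misidentification, spatial structure within areas,
seasonality beyond photoperiod, abundance covariation between groups, and
temporal autocorrelation across survey years. Passing recovery tests on
these simulations therefore shows the estimators are correct under the
stated model, not that real data meet its assumptions.

## Validation studies and their problem sizes

The test-suite recovery studies use sizes chosen to make the checks sharp
yet quick to reproduce: the multinomial study uses 50 replicate communities
of 24 species, 10,000 events over 8 areas (per replicate: the interaction
model should win the AIC ranking, and ±2 SE intervals around the four
guild-specific night slopes should cover the truth at near-nominal rate);
the coupling study uses 100 replicates each of ±0.2 coupling at 11 areas
plus 200 null replicates for the type-I rate. Solar accuracy is checked
against an independently written Michalsky-scan oracle on a 7-latitude x
12-month grid, and the overlap estimators against adaptive quadrature on
exact von Mises densities.

## Known limitations

* The Laplace approximation is excellent for the large per-area counts
  typical here, but with very few events per area the variance estimates
  can be boundary-biased (σ → 0).
* Wald CIs (GLMM) and asymptotic-normal prediction intervals (multinomial)
  are first-order; profile or bootstrap alternatives are not implemented.
* The independence filter's 1 h window is a convention, not an estimate of
  behavioural independence.
* No phylogenetic correction: species enter as independent replicates
  within guilds.
* The twilight category is rare by construction (~5-45 min bands), so
  twilight-equation coefficients are the least stable part of any fit.
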