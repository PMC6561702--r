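---
title: "Modelling wind-limited landing in cliff-nesting auks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wind-limited landing in cliff-nesting auks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliffwind)
```

## The problem

Guillemots and razorbills land on narrow cliff ledges at high airspeed and
with low manoeuvrability. An approach either ends with the bird touching
down and stopping flight (a success) or with a last-moment abort, after
which the bird flies a loop — median 34 s — and tries again. The questions
this package addresses are: how does the probability of a successful
attempt depend on wind and on the landing site; how many attempts does a
bird need under a given mean wind climate; and what does the repetition
cost energetically?

The package has three linked layers — an observational model fitted to
per-attempt data, a probabilistic model of repeated attempts built on top
of the fitted coefficients, and the wind post-processing that connects
cliff-side conditions to open-water wind records — plus circular
statistics for colony orientation and a synthetic-data generator that
stands in for field observations.

## Wind quantities

Airflow model output provides a mean wind speed $U$ and a turbulent
kinetic energy $k$ at each point. Assuming isotropy of the fluctuations,
a typical velocity perturbation is $u = \sqrt{(2/3)\,k/\rho}$, and its
ratio to the mean, the turbulence intensity $I = u/U$, is the
dimensionless measure of gustiness used throughout (about 0.1 in ordinary
terrain, approaching 1 in sheltered, recirculating air). The density
$\rho$ defaults to 1 kg m$^{-3}$, so normalised flow-model output can be
used directly.

Two further standard conversions are provided. Anemometer records are
moved between heights with the neutral logarithmic profile
$U_2 = U_1 \ln(z_2/z_0)/\ln(z_1/z_0)$; the over-land roughness length is
0.1 m (the value used in the airflow modelling), the over-sea default
0.001 m (configurable — a typical open-water value, since no measured one
is available). Open-water and cliff-side winds are linked by a scaling
constant computed as the mean over wind directions of the per-direction
ratio (cliff speed / at-sea speed): mean-of-ratios rather than
ratio-of-means, because each direction's flow field is normalised by its
own upwind reference. The pipeline default ratio of 0.5 is the package's
own choice, fixed once from the typical near-cliff medians
(2.1–3.5 m s$^{-1}$) against the open-water seasonal median
(6.1 m s$^{-1}$); the true constants depend on colony and direction and
should be recomputed from paired flow samples when available.

## The observational model

Landing success is Bernoulli per attempt and modelled on the logit scale
with `lme4::glmer` (Laplace approximation, bobyqa optimiser):

$$\mathrm{logit}\,\Pr(\text{success}) = \beta_0 + \beta_w w_c +
\beta_t t_c + \text{ledge} + \text{species} + \text{height} +
w_c{\times}\text{ledge} + t_c{\times}\text{ledge} + b_{\text{day:colony}}$$

where $w_c$ and $t_c$ are wind and turbulence centred at their sample
means (centring removes the collinearity between main effects and their
interactions and is undone automatically when predicting from raw winds),
and $b$ is a Normal random intercept shared by all attempts at one colony
on one day — the grain at which wind direction and local topography
jointly set conditions. Baselines are the large ledge class, guillemots,
and the top height band; ledge classes are `large` (wider and deeper than
a bird), `long_narrow` (wider but not deeper) and `small` (smaller than a
bird in both directions); height bands `h1`–`h4` run bottom to top. The
height baseline is a genuine free choice (reported offsets elsewhere
identify only the lowest band); the top band was fixed as reference so
that the one clearly attested contrast, the lowest-band deficit, appears
directly as a coefficient.

Model summaries include: a sequential (Type-I) analysis of deviance in
the fixed reporting order wind, ledge, turbulence, species, height,
wind×ledge, turbulence×ledge, each term's drop in deviance expressed per
degree of freedom (an F-like statistic) and as a percentage of the
deviance of the null model (intercept plus random intercept) — sequential
because a term-by-term F/deviance listing implies entry order, and this
order puts the focal predictor first; variance-partition $R^2$ on the
latent scale, $R^2_m = \sigma^2_f/(\sigma^2_f + \sigma^2_b + \pi^2/3)$
marginal and $R^2_c$ adding $\sigma^2_b$ to the numerator; Pearson
chi-squared tests (no continuity correction) for species differences in
ledge and height use; and a basic simulated-residual check
(probability-integral-transform residuals against replicate simulations
from the fitted model, tested for uniformity) standing in for a full
residual-diagnostic suite. AIC counts the random-intercept variance as
one parameter.

Predictions are population-level (random intercept 0) by default; an
option marginalises over the intercept distribution by quadrature. The
two differ visibly when $\sigma_b$ is large, and which a published curve
shows is often unstated — both are therefore available.

## The probabilistic attempt model

For a fixed profile (ledge, species, height, turbulence held at a fixed
value) the fitted linear predictor is linear in raw wind, so success is
exactly

$$p(W) = \frac{a}{a + e^{bW}},$$

with $b$ the negated total wind slope (main effect plus the profile's
ledge interaction — negated so that $b > 0$ corresponds to success
declining with wind) and $\ln a$ the linear predictor at $W = 0$.
`logistic_from_glmm()` performs this collapse and reproduces
`predict_success()` to machine precision; the identity is tested.

A bird making repeated attempts under a stationary wind climate samples
an instantaneous wind per attempt, modelled as
$W \sim \mathrm{LogNormal}(m, s^2)$ with $m, s$ chosen by moment matching
so that $W$ has mean $U$ and standard deviation $u = I \cdot U$:
$s^2 = \ln(1 + u^2/U^2)$, $m = \ln U - s^2/2$. The per-attempt success
probability is then

$$P = E[p(W)] = \int_0^\infty p(W)\, f_{\mathrm{LN}}(W; m, s)\, dW,$$

and the attempt count is geometric: $\Pr(S = n) = (1-P)^{n-1}P$, expected
attempts $1/P$. Successive attempts are treated as independent draws — a
deliberate simplification; within-bout wind autocorrelation would stretch
both tails of the attempt distribution and is out of scope.

Numerics: the integral is evaluated on the standardised log scale
$z = (\ln W - m)/s$, where the integrand $p(e^{m+sz})\varphi(z)$ is
smooth and bounded by the Gaussian density; adaptive quadrature runs over
$z \in [-12, 12]$ at absolute tolerance $10^{-10}$, the truncated Gaussian
tail ($< 4\times10^{-33}$) bounding the truncation error. The degenerate
case $u = 0$ returns $p(U)$ exactly, and a flat curve ($b = 0$) is
short-circuited to avoid $0\cdot\infty$ at the transform limits. A
Monte-Carlo companion (`mean_landing_prob_mc`) provides an independent
estimate with a standard error; quadrature and oracle are required to
agree within sampling error across random parameter sets in the tests.

`landing_curve_at_sea()` chains the pieces: at-sea wind → cliff wind via
the scaling ratio → fluctuation SD via a fixed turbulence intensity
(default 0.2, a representative cliff-side value) → $P$ → cumulative
landing probabilities for attempts 1..20 (20 being roughly the most a
guillemot needs near the seasonal maximum wind).

## Energetics

Costs are deliberately parametric: flight power (W) and prey energy (kJ)
come from the literature and enter only through the configuration, since
they are measured elsewhere; the package computes products and ratios.
With the default power of 144.1 W — the value implied by a 4.9 kJ loop of
34 s — a bout at per-attempt success $P$ costs $4.9/P$ kJ in expectation,
and one ~29.4 kJ sandeel buys about six loops.

## Colony orientation

Bearings are summarised by the mean resultant length
$\bar R = |n^{-1}\sum e^{i\theta_j}|$ and mean direction; uniformity is
tested with the Rayleigh statistic $Z = n\bar R^2$ and the second-order
corrected p-value, which the tests verify against a simulated null to
within 0.01 for $n$ of 5–50. Both $\bar R$ and $Z$ are reported, because
summaries in the literature occasionally print the resultant length in
the statistic's position — for $n = 11$, $\bar R = 0.314$ the corrected
p-value is 0.346, whereas reading 0.314 as $Z$ would give
$p \approx 0.73$; reporting both removes the ambiguity.

## The synthetic-data generator

`generate_observations()` inverts the observational model: covariates are
drawn from configured frequencies, the linear predictor is assembled from
the configured logit-scale coefficients on centred predictors, a Normal
(day, colony) intercept is added, and Bernoulli outcomes are drawn. The
generating truth (coefficients, centring values, realised intercepts)
travels with the table so tests can compare recovered against generating
values.

Default conditions emulate the field setting: 6000 attempts over 5
colonies and 26 days; wind coefficient $-0.62$ per m s$^{-1}$, ledge
offsets $-1.21$ (long-narrow) and $-2.48$ (small), turbulence $-0.81$,
razorbill $+1.10$, lowest-height $-0.58$, wind×ledge $+0.03$/$+0.22$ and
turbulence×ledge $+0.95$/$+0.07$; a random-intercept SD of 0.5 (chosen to
give a marginal-to-conditional $R^2$ gap of about 0.05 on the latent
scale); long-narrow ledges ~47% of attempts and razorbills biased toward
the smallest ledges and higher bands; about 69% of attempts by
guillemots. The intercept (2.8) and the two unreported middle height
bands ($-0.3$, $-0.1$) are the package's own settings, fixed so that
success is near-certain on large ledges in still air and falls below 20%
at 8 m s$^{-1}$ on long-narrow ledges. Wind is hierarchical: each
(day, colony) draws a log-normal daily mean around the 3 m s$^{-1}$
climate (CV 0.5, spanning roughly the observed 0–12 m s$^{-1}$ range and
giving a wind-coefficient SE near 0.05 at $n = 6000$), and per-minute
readings fluctuate around it with turbulence intensity 0.2; the
turbulence covariate varies at the (day, colony) level (CV 0.5), since a
site's gustiness is set by the day's wind direction. Per-colony daily
attempt volumes are not documented anywhere, so attempts are simply
assigned uniformly to (day, colony) cells.

What the generator does *not* emulate: spatial airflow physics (the
gridded $(U, k)$ fixture is purely statistical — smooth fields with
near-constant fluctuation magnitude, so intensity peaks where the mean
wind is weak, as around real topography); temporal autocorrelation of
wind within a session; repeated attempts by identifiable individuals; and
observer effects. Passing tests therefore demonstrate that the estimation
and propagation machinery is correct under the stated model, not that the
model is adequate for any particular field dataset.

One master seed drives everything; independent substreams derive from it
by the fixed rule `seed + 10007 * stage_index (mod 2^31 - 1)`, so every
pipeline stage is individually reproducible.

## Problem sizes and tolerances

The test suite works at the scale of the study itself: single fits and a
50-replicate interval-coverage simulation at $n = 6000$, quadrature
against a $10^6$-draw oracle over random parameter sets, $10^4$-resample
nulls for the Rayleigh p-value, and $10^5$-draw moment checks for the
wind sampler. Closed-form identities (moment matching, geometric
arithmetic, the collapse identity) are asserted at $10^{-10}$–$10^{-12}$;
stochastic checks at 2–3 standard errors of their own noise. Likelihood
invariance under predictor shifts is asserted at $10^{-8}$, coefficient
invariance at 1% of a standard error — iterative optimisers move weakly
identified coefficients more than the likelihood under bit-level input
changes.

## Known limitations

* The deviance-decomposition percentages depend on the entry order
  (sequential by design) and on how much covariate variation the random
  intercept absorbs; with strongly day-structured wind the wind term's
  share understates the total wind signal.
* Separation and non-convergence are detected heuristically (extreme
  coefficients/SEs, optimiser codes) and flagged, not resolved.
* The geometric attempt model ignores behavioural state: real birds may
  give up, queue, or change target ledge between attempts.
* Energetic conclusions inherit the uncertainty of the literature values
  for flight power and prey energy; only products and ratios are
  computed here.
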