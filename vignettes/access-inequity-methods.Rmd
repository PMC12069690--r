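---
title: "Models and methods for mapping inequities in access to HIV treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for mapping inequities in access to HIV treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(accessmap)
```

This vignette documents the statistical machinery in `accessmap`: the
survey-design model, the travel-time distribution model, the geostatistical
stage, the synthetic-country generator that underpins all validation, and
the numerical and design choices made where several defensible options
existed.

## The setting

National HIV impact surveys in sub-Saharan Africa interview tens of
thousands of adults under a two-stage stratified cluster design: census
enumeration areas (EAs) are drawn within urban/rural strata with
probability proportional to population, then households within EAs.
Biomarkers establish HIV status and, for people with HIV (PWH), whether
antiretrovirals are present in blood ("on ART"). People on ART report
their one-way travel time to the clinic in three coarse bands: under one
hour, one to two hours, more than two hours. Cluster coordinates are
released only after random displacement (geomasking). The package asks, and
makes testable, the questions such data support: who carries the infection
burden, who is treated, how long must the treated travel, and where would
treatment have to reach to cover a target share of all PWH.

## Design-based estimation

All prevalence and coverage estimates are ratio means
$\hat\theta = \sum w_i y_i / \sum w_i$ under the released design weights.
Variance uses the stratified delete-one-PSU jackknife (JKn): replicate
$(h,i)$ removes PSU $i$ of stratum $h$, reweights the remaining PSUs of
$h$ by $n_h/(n_h-1)$, and

$$\widehat{\mathrm{var}}(\hat\theta) = \sum_h \frac{n_h-1}{n_h}
  \sum_{i \in h} \bigl(\hat\theta_{(hi)} - \hat\theta\bigr)^2 .$$

Confidence intervals are $\hat\theta \pm t_{df,0.975}\,\mathrm{se}$ with
$df = \#\mathrm{PSUs} - \#\mathrm{strata}$, the standard survey-software
convention. For a single stratum of $n$ equally weighted PSUs this reduces
exactly to the classic $s^2/n$ for a mean — one of the package's frozen
oracle tests.

Group differences use a one-degree-of-freedom Wald statistic
$F = (\hat\theta_a - \hat\theta_b)^2 / \widehat{\mathrm{var}}(\hat\theta_a -
\hat\theta_b)$ referred to $F(1, df)$. Crucially the contrast itself is
jackknifed: both domain means are re-estimated under every replicate, so
the covariance induced by PSUs contributing to both domains is captured.
Summing the two domain variances would ignore it; when the domains occupy
disjoint strata the two computations agree exactly, which is tested. A
Rao–Scott-corrected test is a known alternative; the plain Wald form is the
default because it is exactly reproducible from replicate weights alone.
Domains under 25 unweighted records trigger a small-domain warning
(threshold configurable).

## Travel-time distributions from censored categories

The three reported bands are interval censoring of a latent travel time.
The package represents a group's distribution by a logistic CDF
$F(t) = \mathrm{logit}^{-1}\!\bigl((t-\mu)/s\bigr)$, with $\mu$ the median
travel time (hours) and $s$ the scale. The weighted category shares give
cumulative anchors $(1, p_{<1})$, $(2, p_{<2})$ and an endpoint anchor
$(T_{end}, 1)$ at 3.5 h for urban domains and 4 h for rural ones —
rural journeys have the longer tail; national domains use the rural
endpoint 4 h since a national curve must accommodate that tail.

Fitting minimises $\sum_i w_i (F(t_i) - p_i)^2$ over $(\mu, \log s)$ by
BFGS with analytic gradients, started at the exact closed-form solution
through the two outermost interior anchors:
$1/s = [\mathrm{logit}(p_2) - \mathrm{logit}(p_1)]/(t_2 - t_1)$,
$\mu = t_1 - s\,\mathrm{logit}(p_1)$. With two anchors the fit reproduces
this solve to $10^{-10}$; with anchors generated from a known curve it
recovers $(\mu, s)$ with residual below $10^{-12}$. Numerical choices worth
stating:

* anchor weights are equal by default — the anchors are already
  domain-level summaries, so unequal weighting would double-count sample
  size; a `w` column lets users override this;
* cumulative proportions exactly 0 or 1 are clipped by $10^{-9}$ before
  fitting, because a logistic CDF attains them only as $s \to 0$; a fully
  censored tail therefore degrades to a steep but finite curve rather than
  a failed fit, reported with `converged = FALSE` when the iteration cap
  is hit with an essentially perfect residual;
* an interval-censored multinomial MLE is a defensible alternative to
  anchored least squares; least squares on the cumulative points is the
  default because it is the direct mathematical transcription of the
  plotted construction, and at these sample sizes the two differ well
  below the sampling noise.

Confidence bands are cluster bootstrap: EAs resampled with replacement
within strata, the table re-tabulated and the curve refitted, `B = 1000`
replicates by default, pointwise 2.5/97.5 percentiles on a 0–5 h grid.
Resampling PSUs rather than individuals respects the design's clustering;
degenerate replicates (an emptied category) are skipped and counted, and
more than 20% skipped aborts the band. Band width scales approximately as
$1/\sqrt{\#\mathrm{PSUs}}$, which is checked by simulation.

The odds-ratio model is a logistic regression of travelling one hour or
more on rural residence, female sex and the four age-band dummies, fitted
among on-ART records that answered the item. The default is unweighted
maximum likelihood; a design-weighted mode (weights normalised to mean 1,
PSU-clustered sandwich standard errors) is provided. Coefficients beyond
±15 on the logit scale are treated as separation and refused by name. On a
collapsed 2×2 table the fitted odds ratio equals the cross-product ratio
to $10^{-6}$, another frozen oracle.

## The geostatistical stage

Cluster prevalence points (EA-level weighted means at geomasked
coordinates) are interpolated by **local ordinary kriging**. The empirical
semivariogram uses the Matheron estimator in equal-width distance bins up
to half the maximum pair distance; an exponential (default) or spherical
model is fitted by weighted least squares with weights
$N(h)/h^2$. Each grid cell is predicted from its `k = 15` nearest points by
solving the OK system with a Lagrange multiplier, so weights sum to one;
predictions of a proportion are clamped to $[0,1]$; a singular
neighbourhood matrix is retried once with a $10^{-10}$ diagonal jitter,
then set to nodata. With `k = n` the local solver equals a full-matrix
solve to $10^{-6}$, which is tested against an independently coded oracle.

The production systems behind published prevalence surfaces often use
empirical Bayesian kriging, an ensemble over simulated semivariograms with
proprietary internals. The package approximates that behaviour with an
optional ensemble mode — variograms refitted on bootstrap subsets of the
points, predictions and variances averaged — and is otherwise plain OK, so
surfaces built here reproduce published maps approximately, not
bit-exactly. Kriging is performed on the raw proportion scale with
clamping by default; prevalence here is far from 0/1 so the
transform matters little, and an empirical-logit mode can be built from
the same primitives.

Leave-one-out cross-validation reports mean error, RMSE, mean and RMS
standardized errors and average kriging SE. Under a correctly specified
model the standardized errors have roughly unit scale: the suite simulates
a Gaussian random field, runs LOO and requires
$|\mathrm{ME_{std}}| < 0.1$ and $\mathrm{RMS_{std}} \in [0.8, 1.2]$.

The DoI raster is the cellwise product of the prevalence surface and the
1 km² population grid — PWH per km² — with nodata propagating; its total
equals the population-weighted mean prevalence times total population, an
algebraic identity tested to $10^{-9}$. Ranking cells by DoI and
accumulating their share of all PWH gives the epidemic concentration
curve; the coverage solver returns the DoI value of the first ranked cell
at which the cumulative share reaches the target, i.e. the minimum density
that must be on treatment to achieve that coverage by saturating the
densest cells first. Ties in the ranking are broken arbitrarily — they
produce identical thresholds — and zero cells count in the total but
cannot appear on a log-scaled plot. Default coverage targets are
76.6%, 70.0% and 62.6%, the current national treatment-coverage levels of
the three countries this style of analysis is applied to.

## The synthetic country

The generator exists so that every estimator above has a recoverable
ground truth. What it emulates, and its defaults:

* **Population** (`generate_population_grid`): a 40×40 km grid of 1 km²
  cells, rural background 250 persons (aged 15–59) per km², three urban
  cores as Gaussian bumps (peak 5000/km², spread 3 km); cells are marked
  urban in descending density until 30% of the population is urban.
  Realistic in scale for a small high-burden country; deliberately flat
  geography.
* **Prevalence** (`generate_prevalence_field`): logit-scale Gaussian
  random field, mean $\mathrm{logit}(0.12)$, exponential covariance with
  sd 0.5 and range 10 km, realised exactly by Cholesky factorisation
  (capped at 10,000 cells — ample at these scales), plus a +0.25 urban
  logit shift. The empirical semivariance of the generated field at the
  range matches the closed form $\sigma^2(1-e^{-1})$ in tests.
* **Survey** (`draw_survey`): EAs by probability-proportional-to-size
  systematic sampling on a randomised list within stratum (inclusion
  probabilities capped at 1), 50 EAs × 100 individuals; design weight =
  inverse inclusion probability, making the weighted record total equal
  the population total. Sex effect: ±0.25 on the logit of the cell
  prevalence (women higher), matching the magnitude seen in the region's
  surveys. ART coverage by sex × residence between 0.66 and 0.80.
* **Travel times**: latent logistic, truncated at zero — the paper-style
  fitted family made well-specified near the origin — with rural
  (μ=1.3–1.4 h) longer than urban (μ=0.7–0.8 h) and women slightly longer
  than men; discretised at 1 h and 2 h; 7% of answers removed completely
  at random (a 93% item response).
* **Geomasking** (`geomask`): random azimuth, distance up to 2 km urban
  and 5 km rural with 1% of rural sites displaced 5–10 km. This is the
  household-survey (DHS-style) convention; the magnitude used by the real
  surveys is not published, so this is an assumption, and true coordinates
  are kept internally for validation only.
* **Replicate weights** (`make_replicate_weights`): one JKn replicate per
  PSU as described above, serialized as `rw001…` columns.

What the generator does **not** emulate: real geography and projections
(the grid is flat km²), household structure and household-level
nonresponse, age-structured epidemiology (age groups are sampled
independently of HIV status), informative item nonresponse, and any
spatial structure in ART coverage beyond sex × residence. Passing tests
therefore demonstrate correctness of the estimators under a clean,
design-faithful data-generating process — not robustness to the messiness
of real field data.

## Validation scales

The test suite's Monte-Carlo checks use sizes chosen to make sampling
noise small relative to the tested tolerance while keeping the default
run fast: 200 survey replications of 50 EAs × 100 individuals for CI
coverage (≥90%) and F-test size (binomial bounds around 5%); ~100,000
treated draws for travel-time recovery within 0.01; 200 points for kriging
calibration; 40 points for the exact full-system comparison. The
acceptance script runs the complete default pipeline from a single seed
and reports every headline quantity as JSON, computed at run time.

## Known limitations

* The travel-time tail beyond two hours is identified only through the
  endpoint-anchor convention; different endpoint choices shift μ and s for
  heavy-tailed domains.
* Kriging treats cluster prevalence as point observations; the binomial
  noise of small clusters enters only through the fitted nugget, not an
  explicit measurement-error model.
* Geomasked coordinates are used as-is; kriging is fairly robust to such
  displacement, but estimates near sharp urban gradients inherit it.
* The F-test and CIs rely on large-PSU asymptotics; with few PSUs per
  stratum the t-approximation on PSUs − strata df is the main safeguard.
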