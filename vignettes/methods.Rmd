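---
title: "Methods: modelling change in assemblage abundance and biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling change in assemblage abundance and biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

National bird monitoring produces two complementary kinds of data per
species: **annual index series** (relative abundance with standard errors,
meaningful only as ratios between years) and **absolute population
estimates** (counts of breeding individuals anchored to a reference year,
often given as a minimum--maximum range). Neither alone can say how many
individuals an assemblage has gained or lost. `avitrend` combines them:
index series give each species' trajectory shape, population estimates give
its absolute scale, and a Bayesian hierarchical model propagates the
uncertainty of both into posterior trajectories of total abundance, from
which biomass trajectories, change decompositions, breakpoint analyses and
trait-correlate models follow.

# Series preparation

Raw index series pass through fixed inclusion rules before any modelling:

* **Zero handling.** A series is retained from the year of its first
  positive count. If zeros remain in the retained window, 1% of the mean of
  the retained raw values is added to every value, so logs exist everywhere.
  The mean is taken over the retained (post-truncation) window, not the full
  raw series, keeping the offset on the scale of the data actually analysed.
* **Coverage.** A species is excluded when the most recent year of its
  series represents less than 50% of the regional population; individual
  years covering less than 5% are dropped.
* **Span.** Series whose first and last years are less than 10 years apart
  are excluded (a span of exactly 10 years is retained).
* **Named exclusions** (species an analyst removes for known data problems)
  come from a configuration list, never from hard-coded names.

The full preparation is idempotent, and every exclusion carries a
machine-readable reason. The 1% offset applies only when zeros remain
*after* truncation; zeros confined to the pre-truncation years trigger no
offset, since they never enter the analysis.

# Trend expansion

Where a species has no annual index but a reported mean multiplicative
trend $\bar T$ over a trend period, a mean population estimate
$\bar{E}N_{\bar y}$ and a mean estimate year $\bar y$, its annual national
series is reconstructed as
$$\bar{E}N_i = \bar{E}N_{\bar y}\,\lambda^{(i-\bar y)}, \qquad
  \lambda = \bar T^{1/\text{trend period}},$$
then summed across countries. Uncertainty comes from a percentile bootstrap
(default 1000 replicates, 2.5/97.5 percentiles): population estimates are
redrawn lognormally with median equal to the reported value and log-sd
matched to the standard error by the delta method
($\text{sdlog} = \text{se}/\text{estimate}$), independently across
countries. The lognormal respects positivity; nothing in the inputs
supports cross-country correlation, so none is imposed. Regional point
estimates from summed national bounds use the geometric mean
$\sqrt{\min\times\max}$ with standard error $(\max-\min)/6$; a best-only
value acts as both bounds and has zero standard error.

# Smoothing

Each prepared series is smoothed on the log scale with a penalized cubic
regression spline (`mgcv::gam`), weighted by the inverse squared log-scale
standard errors ($\text{se}_{\log} = \text{se}/\text{index}$). The supplied
SEs are treated as *known* observation standard deviations (the GAM scale
parameter is fixed at 1), so the smoothing parameter is chosen by the
known-variance (Mallows $C_p$/UBRE) form of generalized cross-validation
and fitted standard errors are monotone in the weights. The basis dimension
defaults to $\min(10, \lceil n/3\rceil)$ --- standard practice that
prevents a short series from being overfitted. Fitted values and SEs are
returned at every calendar year in the span, including interior years with
no data. Series with fewer than four observations fall back to a flagged
weighted log-linear fit.

A species' **average annual growth rate** is the endpoint log difference of
its smoothed series divided by the span in years. Endpoints (rather than
the mean of year-on-year rates) match the "average annual rate of change"
reading and make the rate independent of interior wiggles; by default the
rate is computed over each species' full series.

# The hierarchical abundance model

The package commits to one concrete generative model (its canonical
variant):

$$
\begin{aligned}
x_{s,y} &\sim \mathcal N(\lambda_{s,y},\, v_{s,y})
  &&\text{(observation layer)}\\
\lambda_{s,y} &\sim \mathcal N(\theta_s (y - r_s),\, \sigma_{d,s}^2),
  \qquad \lambda_{s,r_s} = 0
  &&\text{(latent trajectories)}\\
\theta_s &\sim \mathcal N(\mu + a_{h(s)} + b_{m(s)} + g_{h(s),m(s)},\,
  \tau^2)
  &&\text{(species growth, shrunk to groups)}\\
P_s &\sim \text{Lognormal}(\log \text{point}_s,\,
  (\text{se}_s/\text{point}_s)^2)
  &&\text{(reference population)}
\end{aligned}
$$

where $x_{s,y}$ is the log index relative to the species' reference year
$r_s$ (the midpoint of the estimate's reference-year range, rounded down),
$h(s)$ and $m(s)$ are habitat and migration classes, and totals per
posterior draw are $T_y = \sum_s w_s P_s e^{\lambda_{s,y}}$ (weights of one
for abundance, body mass in tonnes for biomass).

Design choices that matter:

* **Observation layer.** By default ($\texttt{obs\_layer = "raw"}$) the
  observations are the *raw* log index values with their reported SEs,
  anchored by subtracting the *smoothed* value at the reference year (a
  single raw value would inject its own noise into every year; a shared
  anchor error cancels from every ratio-based quantity). The alternative
  layer on the smoothed values with SEs floored at the raw SEs is kept as
  an option. The raw layer is the default because a penalized smoother
  attenuates genuine smooth fluctuations near the series endpoints and its
  reported SE excludes that bias, which sits exactly where totals are read
  off; with the raw layer, the posterior error of a latent endpoint value
  is $\sigma^2 v/(\sigma^2+v)$ — identical to what the model claims — and
  synthetic-truth z-scores of endpoint change have unit standard deviation,
  whereas the smoothed layer understates them by roughly a third.
* **Missing years.** Grid years without data (leading, trailing or
  interior) are filled with the nearest observed value and their variance
  inflated by the squared number of years since non-missing data (scale
  $c$, defaulting to the species' mean observed log-scale SE), so a value
  ten years beyond the data carries essentially no information and the
  species' group mean takes over.
* **Group structure.** Additive habitat and migration effects plus an
  interaction with its own precision, rather than fully saturated
  habitat-by-migration cells: small cells stay identifiable while a genuine
  interaction can still emerge. $\mu$ and the group effects are additively
  confounded (only their sums enter $\theta_s$); convergence is therefore
  monitored on identified quantities (log totals, mean growth, $\tau$),
  with split-$\widehat R \le 1.05$ expected and a warning otherwise.
* **Per-species deviation variances.** $\sigma_{d,s}^2$ follows an
  inverse-Gamma with a Gamma hyperprior on its rate, pooling hierarchically
  across species. Species trajectories deviate from their linear trend by
  smooth fluctuations whose size varies with the trend itself; a single
  pooled variance under-covers strongly fluctuating (often dominant)
  species, while fully independent per-species variances collapse for
  near-linear series. Both failure modes were observed on synthetic data;
  the hierarchical form fixes both.
* **Sampling.** Every full conditional is conjugate, so the posterior is
  explored with a Gibbs sampler (default 4 chains, 1000 warmup, 1000
  retained thinned by 4). The species growth rates are drawn with the
  latent trajectories marginalized out (a blocked update): the
  one-at-a-time conditional couples $\theta_s$ to the filled-year
  $\lambda$s, which sit at the largest $|y - r_s|$ and would otherwise mix
  very slowly. Priors on variances are diffuse inverse-Gammas
  ($a=b=0.001$) except the group-effect scales, which get weakly
  informative IG(1, 0.01) to keep few-level factors stable. Degenerate
  inputs (zero-noise series, zero-SE estimates) collapse the posterior onto
  the exact answer; observation variances are floored at $10^{-12}$.

# Biomass

Biomass is exact linear scaling: population times average body mass (grams
to tonnes, $\times 10^{-6}$), per species, with mass treated as
time-invariant. The biomass trajectory is the abundance trajectory with
mass weights, draw by draw, so every accounting identity carries over
unchanged.

# Climate suitability trends

A species' CST is the slope of an ordinary least-squares regression of
logit(mean annual climate suitability) on calendar year. Suitability values
are clamped into $[10^{-6}, 1-10^{-6}]$ (with a warning) before the logit.
The suitability model provided here is a single logistic GLM with linear
and quadratic terms per climate covariate; complete separation triggers a
ridge-penalized refit. Any external SDM's annual suitability series can be
supplied directly, since only the series enters the CST.

# Trait-correlate models

The global model regresses the log annual growth rate on migration
strategy, habitat, z-scored log body mass, z-scored CST, trophic niche and
abundance class, with the six two-way interactions of the factors with the
continuous variables. Continuous predictors are z-transformed with the
population-SD convention. Marine-habitat species and species without a CST
are excluded (with counts reported). Abundance classes are equal-count
quartiles of the population point estimate --- rare, scarce, common,
abundant --- with any remainder allocated to the rarer classes so
"abundant" is always exactly the top quartile; the point estimate (not the
maximum) defines the ranking. "Trophic level" and "trophic niche" are
treated as a single categorical variable.

PGLS uses the Brownian covariance of the tree with off-diagonals multiplied
by Pagel's $\lambda$, estimated by maximum likelihood on a $[0,1]$ grid
refined by golden-section search, with a profile confidence interval at a
1.92 log-likelihood drop and boundary likelihood-ratio tests against 0 and
1 referred to a 50:50 mixture of $\chi^2_0$ and $\chi^2_1$. Coefficient
standard errors use the $n-p$ denominator so the $\lambda = 0$ fit on an
ultrametric tree reproduces ordinary least squares exactly; the AIC uses
the ML log-likelihood with $\lambda$ counted as a parameter when estimated.
Branch lengths are assumed proportional to expected covariance; a star
phylogeny makes $\lambda$ unidentifiable and is flagged, with the fit
reverting to OLS.

All-subsets selection enumerates every marginality-respecting
simplification of the global model, ranks by AIC (AICc is available by
refitting with it; plain AIC is the default to match "information criterion
units"), removes any model that contains a simpler retained model with
lower AIC, and retains everything within 6 units of the minimum. The
enumeration refuses more than $10^5$ candidates. Note one property of AIC
selection worth keeping in mind when reading recovery simulations: an
irrelevant predictor is admitted with probability
$P(\chi^2_1 > 2) \approx 0.157$, so even a perfectly behaved procedure
retains a noise term in roughly one replicate in six.

# Breakpoint regression

Two-segment continuous ("hinge") least squares on the log totals: for every
interior candidate year with at least three points per side, fit
$y = b_0 + b_1 x + b_2 (x-c)_+$, keep the SSE minimizer (earliest year on
ties). Slopes are reported as $100\times$ the natural-log slope --- percent
per annum; this convention is fixed and recorded in the output metadata.
Straight-line inputs are flagged degenerate; with no admissible breakpoint
a flagged single-slope fit is returned.

# Change summaries

All decompositions are computed per posterior draw: net change
end-minus-start; increases and decreases summed over species classified by
their own per-draw change, so increase + decrease = net exactly in every
draw and group nets sum to the assemblage net. A species' headline
direction is the sign of its posterior median change. Percent change is
$100(T_{end}-T_{start})/T_{start}$; the per-annum rate is the geometric
$100((T_{end}/T_{start})^{1/\text{span}} - 1)$ with span in calendar years,
which compounds back to the percent change exactly. Published tables
aggregated from posterior medians need not satisfy end-minus-start
arithmetic exactly (medians are not linear); this package reports medians
of per-draw quantities, so its own outputs always reconcile.
Concentration-of-change is the share of the total same-sign change in the
$k$ (default 8) species with the largest changes of that sign.

# The synthetic-data generator

`simulate_assemblage()` defines the study conditions for every test:

* reference abundances lognormal with log-sd 2 (a handful of species
  dominate the total, as in real assemblages);
* log trajectories linear in time (group mean + species deviation,
  $\tau = 0.01$, group SDs 0.01/yr) plus a sinusoidal wiggle with amplitude
  10% of the total trend magnitude and period 8--20 years, so smoothing is
  non-trivially exercised;
* heteroscedastic log-scale observation noise (SD 0.05, varying by ±50%
  across years --- typical of reported index SEs);
* population estimates with lognormal error (log-sd 0.1) at the mid-series
  reference year, with min/max bounds at ±3 log-sd so the span/6
  standard-error rule recovers the generating error exactly (bounds at
  ±1.96 log-sd would make the rule understate the truth and visibly break
  interval calibration);
* 20% of species missing their leading years and 5% with leading zero
  counts, exercising the preparation and missing-variance rules;
* a Yule phylogeny (`ape::rphylo`), optional Brownian trend components and
  optional mass--trend correlation for the trait models; suitability series
  with known logit slopes.

`paper_like_scenario()` is a fixed-seed assemblage of 180 species over 53
years in which abundant, smaller-bodied species decline and rarer, larger
species increase; the two trend coefficients are solved numerically at
generation time so the *true* totals change by exactly −19% (abundance) and
+5% (biomass). The scenario's wiggle has a fixed small amplitude (0.02 log
units) so the endpoint change is linear in the trend coefficients and the
solve is exact.

What passing tests on these data do **not** show: the generator has no
country-level scheme heterogeneity, no taxonomic bias, no correlated
estimate errors across species, and its trajectories really are
linear-plus-sinusoid. Calibration statements (e.g. 95% intervals covering
truth in 93--97 of 100 replicates) are statements about this generative
family, not about any real monitoring dataset.

# Problem sizes and reproducibility

Test and acceptance runs use deliberately modest sizes chosen to exercise
every code path while keeping the suite quick to re-run: calibration uses
100 assemblages of 40 species × 40 years with single-chain reduced MCMC
(300 warmup + 400 retained); the scenario fit uses two chains of 500; PGLS
recovery uses 100-tip trees × 100 replicates. All randomness flows from
explicit integer seeds; a fixed seed reproduces every number bit for bit.

# Known limitations

* The hierarchical model assumes independent observation errors across
  years after smoothing; smooth deviations are absorbed by the per-species
  deviation variances rather than an explicitly autocorrelated process.
* No density dependence, demographic structure or spatial random effects.
* The per-annum rate convention is the geometric rate over the calendar
  span; published per-annum figures computed under other (unstated)
  divisors can differ in the second decimal.
* The SDM stage is a deliberately simple logistic GLM; users with a proper
  SDM ensemble should feed its annual suitability series directly into
  `cst_slope()`.
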