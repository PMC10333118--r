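---
title: "Methods: synthetic-control evaluation of avoided deforestation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-control evaluation of avoided deforestation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestsynth)
```

## The evaluation problem

India's National Tiger Conservation Authority has, since 2007, gazetted
selected protected areas as tiger reserves, bringing enhanced enforcement,
monitoring and funding. `forestsynth` estimates what that upgrade did to
forest loss: for each treated reserve it asks how much cumulative forest
loss *would* have occurred without the intervention, and prices the
difference in avoided CO2-equivalent emissions.

The counterfactual is built with the synthetic control method. For a
treated reserve with intervention year $T_0$ and cumulative loss series
$y_{1t}$ (hectares lost since the first panel year), a weighted combination
of never-treated "donor" reserves from the same landscape grouping is
chosen so that the combination tracks the treated reserve before $T_0$:

$$\hat y_{1t}^{N} = \sum_{j=1}^{J} w_j \, y_{jt}, \qquad
  w_j \ge 0,\; \textstyle\sum_j w_j = 1 .$$

The effect at the evaluation year $T$ (2020 in the study design) is
$\hat\tau = \hat y^{N}_{1T} - y_{1T}$: positive values are averted forest
loss, negative values mean the reserve lost more forest than its
counterfactual.

## The nested estimator

`fit_synthetic()` implements the standard nested form. Matching predictors
are the twelve reserve-level structural drivers of deforestation
(population density, road length, precipitation, elevation, slope, aspect,
baseline aboveground biomass, purchasing power parity, reserve age, travel
time to the nearest city, and total area) plus the mean pre-intervention
cumulative loss. Each predictor is standardized to zero mean and unit
variance over the treated + donor pool; constant predictors are dropped
with a warning.

* **Inner problem** (`inner_weights()`): for fixed predictor weights $v$ on
  the simplex, donor weights solve
  $\min_w (X_1 - X_0 w)^\top \operatorname{diag}(v) (X_1 - X_0 w)$ subject
  to the simplex constraints. The solver seeds a support via non-negative
  least squares on a penalty-row augmented design (Lawson-Hanson, finite
  termination), then runs a primal active-set loop on the exact
  equality-constrained KKT system: step-to-boundary when a subproblem
  solution leaves the feasible region, dual-feasibility releases otherwise,
  with a strict-decrease guard that rules out cycling on degenerate
  instances. A ridge of `1e-11` times the mean Gram diagonal regularizes
  rank-deficient supports (the generic case, since predictors are fewer
  than donors) and makes the tie-break among equivalent optima
  deterministic; a ridge-free refinement on the final support removes the
  regularization bias when the system is well posed.
* **Outer problem**: $v$ is chosen to minimize the pre-intervention MSPE of
  the implied counterfactual. The search runs Nelder-Mead on a softmax
  reparameterization of the $(k-1)$-simplex, started at uniform $v$
  (relative tolerance `1e-8`, at most 500 iterations, both configurable via
  `synth_config()`). Because optima frequently sit at simplex *vertices* —
  all weight on the pre-loss predictor is a common solution — which softmax
  coordinates only reach asymptotically, the optimizer also evaluates every
  vertex as a candidate and restarts from the best vertex when it beats the
  interior search. The reported fit never does worse than the uniform-$v$
  start.

Conventions fixed by the package: the pre-period is all years strictly
before the intervention year; the post-period includes the intervention
year (gazettement takes effect within its year); MSPE is the mean of
squared per-year gaps over the respective period; donors are processed in
sorted id order so results are deterministic; a degenerate zero pre-MSPE is
floored at $10^{-8}$ times the variance of the treated pre-period series
when used as a ratio denominator.

## Inference

Significance uses the exact placebo permutation test
(`placebo_distribution()`): each donor is refitted as a pseudo-treated unit
with the true treated reserve added to its donor pool, and the treated
reserve's post/pre MSPE ratio is ranked (descending, ties taking the worst
rank) among all treated + placebo ratios; $p$ is rank over count. The
attainable floor is $1/(n+1)$ for $n$ placebos, which is why more than 20
donors per landscape grouping are needed to reject at $\alpha = 0.05$
(`minimum_donors_for_alpha(0.05)` returns 20). With 20 or fewer placebos
the ensemble is flagged `cannot_reach_alpha` rather than silently reported.

Covariate balance between treated and donor groups is screened with
pairwise Pearson correlations (pairs flagged at $|r| \ge 0.8$) and an
analysis of similarities (ANOSIM) permutation test on Euclidean distances
of the standardized covariates, delegated to `vegan::anosim()`. Group-level
fit quality is compared with a two-sample bootstrap test of equal means
(`bootstrap_group_test()`, 9,999 iterations by default): both samples are
shifted to the pooled mean, resampled with replacement, and the absolute
mean difference forms the null distribution. No multiple-testing adjustment
is applied across reserves; reported $p$ values are unadjusted by design.

## Robustness battery

* **Anticipation** (`anticipation_check()`): reserves may respond before
  gazettement (the national authority was constituted in 2005). The
  pre-intervention period is split into training (years before the
  backdated pseudo-intervention, default 2005) and testing (pseudo-year up
  to the true intervention year); the panel is truncated at the last true
  pre-intervention year and the full fit + placebo analysis is re-run with
  the pseudo-year as intervention. A significant pseudo-effect excludes the
  reserve. With a 2001 panel start the training window is four years, which
  limits power: placebo fits can overfit such short windows, inflating
  their MSPE ratios, so genuine anticipation of moderate size may escape
  detection. The screen therefore errs conservative (excluding few
  reserves), which matches how it is used — as an exclusion filter, not an
  estimator.
* **Donor trimming** (`trim_donor_pool()`): tiger reserves tend to be
  larger than donor reserves, so fits are repeated keeping only donors at
  least a tenth, and at least a quarter, of the treated reserve's area
  (inclusive boundaries). `concordance()` scores each trimmed refit on
  direction (sign of the effect), magnitude (within ±20% of the full-pool
  effect in hectares) and retained significance; with 20 or fewer donors
  after trimming, significance is reported as not assessable rather than
  failed.

## Carbon accounting

Averted hectares convert to avoided emissions with per-reserve carbon
densities (`carbon_account()`):

* densities referenced to 2010 are rescaled to the intervention year
  proportionally to the forest-cover ratio (`scale_density()`); the
  proportional form is this package's contract — the source phrasing pins
  only that the 2010-to-intervention-year cover change drives the scaling;
* the aboveground component counts each averted hectare at the full
  aboveground density times the IPCC emissions factor 3.67 tCO2e/tC;
* the belowground component decays linearly over 10 years: carbon from a
  hectare lost in year $t$ is only fractionally released by the evaluation
  year, with fraction $\min\{1, (T - t)/10\}$. When only a terminal
  averted-hectares figure is available, increments are spread uniformly
  over the post-intervention years (documented fallback);
* uncertainty is $|\Delta ha| \times 3.67 \times (SE_{AGB} + SE_{BGB})$ —
  additive in the two density standard errors, consistent with the additive
  above/belowground decomposition of the net uncertainty;
* values use US$86/tCO2e (social cost of carbon for India) and
  US$5.8/tCO2e (voluntary-market offset price), reported in thousand US$.

No future land-use scenario, regrowth, degradation or discounting terms are
included. Negative effects flow through the same formulas and surface as
damages and foregone revenue in `aggregate_portfolio()`, whose net is the
sum of gains minus the sum of absolute losses, with uncertainties
aggregated additively.

## The synthetic-data generator

Real inputs to this kind of evaluation are rasters and boundary files;
`simulate_study()` replaces them with a generator whose ground truth is
known exactly, so every stage is testable offline. Its default
configuration mirrors the evaluation's structure: three landscape groups
with 44, 29 and 44 donors, 45 treated reserves, a 2001-2020 panel,
interventions 2007-2015 with roughly half the treated reserves entering in
2007.

Annual loss for reserve $i$ of group $g$ is

$$\ell_{it} = \text{area}_i \times r_0 \times
  \exp(\beta^\top z_i + \gamma_{gt} + \varepsilon_{it}),$$

with $r_0 = 0.001$ (0.1% of area per year, the order of magnitude implied
by reserve-scale losses over two decades), standardized covariates $z_i$
whose default coefficients give roughly one order of magnitude of
between-reserve rate heterogeneity, *group-level year shocks*
$\gamma_{gt} \sim N(0, 0.25^2)$ shared by all reserves of a landscape, and
reserve-level AR(1) shocks $\varepsilon_{it}$ (stationary SD 0.15,
$\phi = 0.5$). The common shocks are essential, not decorative: a
donor-based counterfactual can only reproduce drivers the donors share.
With purely idiosyncratic noise no pre-period-matching estimator can
predict the post period, so a generator without common structure would be
emulating a system in which the synthetic control method is inapplicable.
Treated units multiply their post-intervention rate by $(1-\rho)$;
cumulative loss is the running sum, monotone by construction. The
no-effect counterfactual of every treated unit is simulated with the same
shock sequence, so the injected truth is exact, and everything is
reproducible from a single seed.

Treated and donor areas share one distribution in the generator. Real tiger
reserves tend to be larger than donor reserves; we keep the distributions
equal because a treated unit outside the donor convex hull is structurally
unmatchable — exactly the situation the study's area-trimming robustness
check is designed to probe, and one the generator can produce on demand by
shifting the treated area distribution. Other real-data features the
generator does not emulate: spatial autocorrelation beyond the group level,
India-specific covariate magnitudes, abrupt regime changes (fires,
encroachment waves), and measurement error in the loss maps. Passing
recovery tests therefore demonstrate internal consistency of the estimator
under a favourable but structurally faithful data-generating process, not
field accuracy on any particular landscape.

## Problem sizes and numerical choices

The packaged test-suite and acceptance checks run at study scale chosen for
tight Monte-Carlo behaviour at interactive runtimes: 50-replicate recovery
experiments with 40 donors and 6 pre-intervention years; 200-replicate
placebo calibration with 21 donors on a 12-year panel (every unit refitted
per replicate); 400-replicate bootstrap size checks at group size 30; QP
oracle comparisons on 100 random instances against exhaustive simplex grid
search at step 0.005 (donor counts 2-4, where full enumeration is
tractable). Recovery of a 30% injected loss-rate reduction is unbiased to
within a few percent with these settings; error grows with idiosyncratic
noise, which the suite asserts on a three-point noise grid.

## Known limitations

* Each treated reserve is fitted independently; no pooling across the
  staggered adoption years.
* The anticipation screen has modest power with short training windows
  (see above).
* The MSPE-ratio test rewards good pre-period fits; a treated reserve that
  is intrinsically hard to match (extreme loss levels) can fail to reach
  significance regardless of the true effect.
* Carbon accounting prices stocks, not flows: no discounting over the
  2007-2020 horizon and no forest-degradation emissions.
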