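---
title: "Methods: taxonomic distinctness and richness estimation from Linnean catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomic distinctness and richness estimation from Linnean catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxocat)
```

This vignette documents the models implemented in `taxocat`, the
conventions and defaults they depend on, and what the package's
synthetic-data tests do and do not establish about real catalogs.

## The catalog data model

A catalog is one row per nominal species with its placement at the four
classical ranks below the class (order, family, genus, species epithet),
a description year, and a country list.  Three deliberate restrictions:

* **Sub-ranks are rejected at parse time.**  Subgenera, tribes,
  subfamilies and the like are used too inconsistently across groups to
  carry comparable signal; a header naming them is an error rather than
  a silent drop, so the caller decides how to flatten them.
* **Duplicate species paths are errors, not warnings.**  Synonymy
  resolution is a nomenclatural act outside this package's scope; a
  duplicated (order, family, genus, epithet) path in the input is
  treated as a data defect.
* **Partial records are kept.**  A record with no description year still
  contributes to distinctness (which needs only the classification), and
  a record with no countries still contributes to the time series.  The
  two analyses use disjoint fields, and large catalogs are routinely
  ~15-20% incomplete geographically; discarding partial records would
  bias both.

Species with no family assignment are pooled into a single artificial
`INCERTAE_SEDIS_<ORDER>` family per order by `assign_placeholders()`.
Pooling makes all of an order's unplaced species mutually confamilial,
which *deflates* between-species distance.  That is the conservative
direction: the alternative (a pseudo-family per species) would
manufacture exactly the higher-taxon inflation the distinctness analysis
is trying to measure.

## Average taxonomic distinctness

For a group with $s$ species, average taxonomic distinctness is

$$\Delta^+ = \frac{\sum_{i<j} \omega_{ij}}{s(s-1)/2},$$

the mean over all unordered species pairs of the distinctness weight
$\omega_{ij}$, the tree distance implied by the lowest rank the pair
shares.  The classification tree has four inter-rank steps
(species→genus→family→order→class).

**Step convention.**  The four steps are equal and the longest possible
leaf-to-leaf path is scaled to `max_path` (default 100), so
$\omega \in \{25, 50, 75, 100\}$ for pairs sharing a genus, family,
order, or only the class.  This convention pins the two boundary cases
exactly: an order holding two congeners has $\Delta^+ = 25$ (one pair,
one genus step up and down), and a singleton group is assigned
$\Delta^+ = 0$ — with no pairs to average, zero is a reporting
convention, not a statement that the species is indistinct.  A
`variable_steps` option instead makes each step proportional to the
relative drop in taxon counts between adjacent ranks (ranks that barely
aggregate contribute little path length), still scaled to `max_path`;
it is off by default because equal steps are the common reporting
convention for rank-based trees and make values comparable across
groups with different rank usage.

$\Delta^+$ is computed by counting pairs at each shared rank (pairs
within genera, within families but not genera, and so on), which is
algebraically identical to the double loop over pairs but linear in
$s$.  The test suite verifies the identity against a deliberately naive
pairwise loop on dozens of simulated catalogs (to $10^{-9}$), and
against the independent `vegan` implementation
(`taxa2dist`/`taxondive`) on multi-species groups.  The two singleton
conventions differ: `vegan` reports `NaN` where this package reports 0.

**Regression and overlays.**  `distinctness_regression()` fits ordinary
least squares of $\Delta^+$ on $\log_{10} s$ across groups.  Groups
below `min_species` (default 4) are excluded and listed in the result:
with one or three pairs, $\Delta^+$ is pinned to one or two discrete
values and contributes leverage without information.
`overlay_groups()` places comparison groups against an existing fit
without refitting — the comparison is "where would these taxa sit
relative to the focal group's line", so letting them influence the line
would beg the question.  Residuals within `on_tolerance` (default 0.5
$\Delta^+$ units, about the rounding granularity of published
distinctness tables) are classed as "on" the line so that a qualitative
above/below reading is not driven by numeric noise.

**Replayed group tables.**  `inst/extdata/ordinal_distinctness.csv`
carries published per-order $(\Delta^+, s)$ summaries for the millipede
orders, the centipede orders and the pseudoscorpions, and
`read_distinctness_groups()` lets any such pre-aggregated table drive
the regression directly.  Published order-level $\Delta^+$ values are
replayed rather than recomputed because the underlying catalog is not
publicly deposited, and because published values computed on deeper
rank sets can exceed the within-order maximum of any fixed 4-rank
convention — the regression and overlay layer is therefore designed to
accept group-level summaries as first-class input.

## Richness estimators

### Non-homogeneous Poisson process discovery model

Yearly description counts are modelled as

$$d_t \sim \text{Poisson}\!\big(N\,[F(t+1;\,m,s_c) - F(t;\,m,s_c)]\big),$$

with $N$ the total (described plus undescribed) richness and $F$ a
logistic CDF with midpoint $m$ (the discovery peak year) and scale
$s_c$ (years).  This is the minimal thinned-renewal instantiation that
supports both total-richness estimation and forecasting: effort
variation ("thinning") lives in the data generator, and an optional
per-era effort multiplier can be layered on the rate when needed.

Priors: $N$ log-uniform on [observed count, 50 × observed]; $m$ normal
centred mid-record with sd 100 years; $s_c$ half-normal with scale 50
years.  The cap on $N$ is a pragmatic bound — 50 times the described
count is far beyond any serious proposal for groups with centuries of
records — and the flag below makes the posterior's interaction with the
cap explicit rather than hiding it.

Sampling is adaptive random-walk Metropolis on $(\log N, m, \log s_c)$:
three overdispersed chains; during burn-in the global step size is
tuned toward ~23% acceptance and the proposal covariance is
re-estimated from the chain history, so ridge-shaped posteriors (see
below) are traversed along their long axis.  Convergence is checked
with the split-chain potential scale reduction statistic; any value
above 1.1 is an error carrying the diagnostics, never a silent result.
Defaults (3 chains × 1,500 burn-in + 3,000 kept draws) fit a
250-year record in about a second.

**When there is no asymptote.**  A record still accelerating at its end
constrains only the product of $N$ and the unreached tail of $F$: the
likelihood is flat along a $(N, m)$ ridge and $N$ is bounded only by
the prior cap.  The fit reports `no_finite_estimate = TRUE` when more
than 2.5% of the posterior mass of $N$ lies in the upper half of the
prior range *measured on the log scale* — equivalently, when the 97.5%
credible bound has not been pulled below the geometric midpoint of the
prior range.  The log scale is the right ruler here because the prior
is flat in $\log N$: an unidentified posterior spreads over log-space,
and a criterion phrased on the linear scale (mass in the top few
percent of $[N_{lo}, N_{hi}]$) can miss a completely unbounded
posterior, since the top linear slice is a vanishing fraction of
log-space.  Forecasts remain valid under the flag: near-term rates are
pinned by the recent record even when the asymptote is not.

`forecast_descriptions()` draws posterior-predictive Poisson counts
year by year from the end of the record to the furthest horizon and
accumulates per draw, so forecasts at nested horizons are monotone draw
by draw, and reports the median and 2.5/97.5 percentiles.

### Productivity x-intercept

Plotting each year's new descriptions $d_t$ against the cumulative
total already described $C_{t-1}$ turns "description is slowing down"
into a declining trend whose x-intercept is the projected total
richness.  The estimator fits OLS over the declining phase and reports
$-a/b$; it is exact on a noiseless linear decline by construction.

The declining phase is located by smoothing $d$ against $C$ with a
local-linear tricube-weighted regression (`loess`, degree 1, span 0.75
of points by default) and taking the last point where the smoothed
slope turns negative and stays negative to the end of the record.  A
record whose smoothed slope does not end negative has no declining
phase and the estimator refuses to extrapolate.  A calendar-year
override (`start_year`) is provided because analysts often fix the
window by inspection (e.g. "from 1900 onward") — the automatic detector
makes that choice reproducible instead of manual.

The 95% interval is a percentile bootstrap over the $(C, d)$ points
(2,000 replicates, seeded).  Resampling points treats years as
exchangeable within the window and ignores serial dependence, so the
interval should be read as a regression-stability band, not a full
accounting of uncertainty; no published convention exists for this
estimator's interval.  Two caveats are flagged rather than hidden: an
estimate below the already-described count sets `below_observed`, and
the whole method assumes constant effort — declining effort is
observationally equivalent to approaching completeness, which is why
the NHPP flag above matters as a cross-check.  On logistic histories
the estimator also carries a modest convexity bias (the declining arc
of $d$ vs $C$ is concave, so a chord's x-intercept overshoots
slightly); with a record extending well past the peak this bias is a
few percent.

### Reference-fauna ratio

`extrapolate_from_reference()` multiplies the global-to-regional
richness ratio of a reference taxon considered completely described
(birds, mammals) by the focal group's regional count.  The estimate
inherits the assumption that the focal group's spatial concentration
matches the reference taxon's; no interval is attached because the
dominant uncertainty (that assumption) is structural, not sampling.
Ratios are reported both exact and rounded to 2 decimals, the
conventional reporting precision.

## Geographic effort statistics

Only countries with at least one described species are admitted.  The
tropical/nontropical split is an inclusive 50%-of-land-area rule on an
*input* column — computing tropical land fractions is GIS work outside
this package.  Regressions of per-country species counts on land area
or population use untransformed predictors by default (matching the
usual presentation of such scatter plots) with `log_predictor` /
`log_response` options for power-law fits; named outliers (e.g. the
population outliers India and China) are excluded explicitly and
recorded in the output, and a misspelled exclusion is an error rather
than a silent no-op.  The stratum comparison uses Welch's
unequal-variance $t$ with Welch–Satterthwaite degrees of freedom, plus
per-stratum totals and species-per-km² densities (total species over
total land area, so density × area recovers the total exactly).

Species recorded from several countries count once in each country's
total: the totals are description-record counts per country, not a
partition of species, so stratum totals may exceed the number of
geographically attributed species.  This is the only interpretation
under which published stratum tables are internally consistent
(totals ÷ areas reproduce printed densities).

## Synthetic data: what it emulates, and what it does not

* `simulate_classification()` allocates species to genera (and genera
  to families, families to orders) by a two-parameter
  concentration/discount preferential scheme: an item joins an existing
  block of size $n_k$ with weight $n_k - d$ and opens a new block with
  weight $\theta + d k$.  The discount $d$ produces a power-law block
  tail, so a handful of huge genera coexist with many monotypic ones —
  with the defaults ($\theta = 5$, $d = 0.6$) about 70% of genera in a
  3,000-species catalog hold ≤2 species, the imbalance regime reported
  for large invertebrate catalogs.  A single-parameter scheme cannot
  hit a two-thirds tiny-genus fraction and a moderate mean genus size
  at once, which is why both parameters are exposed; the tests verify
  that varying them brackets a mean of ~4 species/genus and a ~68%
  tiny-genus fraction.
* `simulate_description_history()` gives each of $N$ species a latent
  logistic description year and thins by era-specific effort factors;
  undescribed species stay latent, so described + latent = $N$ exactly
  and estimator error is measured against exact truth.
* `simulate_geography()` draws log-normal areas and populations and
  Poisson species counts with a log link on log area plus a tropical
  effect.  A `count_model = "deterministic"` switch rounds the
  expectation instead of drawing, giving exactly monotone
  richness-in-area for noiseless checks.

These generators match the *model assumptions* of the estimators, which
is precisely what makes them calibration tools: parameter-recovery and
coverage results on them show the machinery is correct, not that real
catalogs satisfy the assumptions.  Real description records have
serially correlated effort (wars, monographers' careers), taxonomic
fashion, and synonymy churn, none of which the generators emulate; the
estimator caveats above are the honest interface to that gap.

## Numerical choices and test scale

* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state (`withr::with_seed`); no global seed is touched.
* Degenerate inputs error early and specifically: empty catalogs,
  single-year series, never-declining records, empty strata,
  zero-variance predictors, out-of-range tropical percentages.
* Pair counting uses exact integer binomials up to catalog sizes far
  beyond any real Linnean catalog; no floating-point pair enumeration.
* The test suite exercises the MCMC at reduced but honest sizes: the
  coverage check runs 20 independent fits of ~250-year records with
  the default 3×4,500-iteration layout (~15 s total), and simulated
  catalogs for oracle checks stay ≤200 species so the brute-force
  double loop remains the visibly-correct reference.

## Known limitations

* $\Delta^+$ here is purely rank-based; branch-length (phylogenetic)
  distinctness, abundance-weighted $\Delta$, and the variance statistic
  $\Lambda^+$ are out of scope.
* The NHPP model fixes a logistic discovery curve; multimodal discovery
  histories (multiple monographic eras) are smoothed over, and the
  per-era effort multiplier is the only relief valve.
* The productivity estimator's bootstrap understates uncertainty under
  serial dependence, and the method cannot distinguish completion from
  abandonment of a field.
* Non-parametric richness estimators (Chao, jackknife) and
  per-author/effort covariate models are deliberately not implemented.
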