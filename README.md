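# taxocat

Tools for asking what a Linnean catalog can say about a species-rich but
understudied group: are its higher taxa (orders, families, genera)
consistent units of diversity, how many species does the group really
contain, and where has descriptive effort been spent?  The package grew
out of the analysis needs of large invertebrate catalogs — millipedes
(Diplopoda) are the motivating case, with >12,000 nominal species,
roughly two-thirds of genera holding only one or two species, and no
deposited global catalog — but every routine works on any table of
`order, family, genus, species, year, countries` records.

Three analysis stages, plus a synthetic-data stage that makes everything
testable without restricted data:

1. **Taxonomic distinctness.** The classification is translated into a
   tree (class → order → family → genus → species) and each group's
   average taxonomic distinctness is computed,

   Δ⁺ = Σᵢ<ⱼ ωᵢⱼ / [s(s−1)/2],

   where ωᵢⱼ is the path distance between species *i* and *j* set by the
   lowest rank they share (four equal steps, longest path scaled to 100:
   congeners 25, confamilials 50, con-ordinals 75, cross-order 100) and
   *s* is the group's species count.  `distinctness_regression()` fits
   Δ⁺ against log₁₀ *s* across groups; `overlay_groups()` places
   comparison taxa on the fitted line without refitting.

2. **Global richness estimation.**  Three estimators driven by the
   description-year record:
   - `fit_nhpp_bayes()` — a non-homogeneous Poisson process discovery
     model, `d_t ~ Poisson(N·[F(t+1) − F(t)])` with logistic discovery
     CDF `F`, fitted by adaptive random-walk Metropolis under a
     log-uniform prior on the total richness `N`; posterior-predictive
     forecasts of future descriptions via `forecast_descriptions()`;
     an explicit `no_finite_estimate` flag when the record shows no
     asymptote.
   - `estimate_richness_productivity()` — regression of yearly
     descriptions `d_t` on the prior cumulative total `C_{t−1}` over the
     declining phase of the record; the x-intercept −a/b is the
     projected total, with a seeded percentile-bootstrap interval.
   - `extrapolate_from_reference()` — global/regional richness ratio of
     a fully described reference fauna (birds, mammals) times the focal
     group's regional richness.

3. **Geographic effort.**  Country-level OLS of described richness on
   land area and population (`richness_regression()`, with named-outlier
   exclusion), a Welch *t* comparison and per-km² description densities
   for tropical (≥50% tropical land) versus nontropical countries
   (`tropical_comparison()`).

Seeded generators (`simulate_classification()`,
`simulate_description_history()`, `simulate_geography()`,
`make_fixture_suite()`) produce catalogs with preferential-allocation
imbalance, thinned logistic discovery histories with known true
richness, and log-area-driven country tables.

## Worked example

Replay the bundled ordinal distinctness table (millipede, centipede and
pseudoscorpion orders) and overlay the non-millipede taxa:

```r
library(taxocat)
groups <- read_distinctness_groups(
  system.file("extdata", "ordinal_distinctness.csv", package = "taxocat"))
fit <- distinctness_regression(groups[groups$taxon_set == "diplopod", ],
                               min_species = 4)
fit
#> Delta+ ~ log10(s): slope 20.962, intercept 23.235
#>   r^2 = 0.5705, p = 0.001785, n = 14
#>   excluded (too few species): Siphonocryptida, Siphoniulida
overlay_groups(fit, groups[groups$taxon_set != "diplopod" & groups$s >= 2, ])
#>   group                 s delta_plus predicted residual position
#> 1 Scutigeromorpha     206       71.6      71.7   -0.129 on
#> 2 Lithobiomorpha     1861       60.9      91.8  -30.9   below
#> 3 Scolopendromorpha  1328       78.3      88.7  -10.4   below
#> 4 Geophilomorpha     1665       90.5      90.8   -0.233 on
#> 5 Pseudoscorpiones   3432       95.6      97.3   -1.73  below
```

The moderate fit (r² ≈ 0.57) says the millipede orders are far from
equally diverse for their size, and every comparison order falls on or
below the millipede line — the millipede classification carries more
higher-taxon structure per species than its relatives.

Richness estimation on a synthetic discovery history with known truth
(15,000 species, logistic discovery peaking in 1900), plus a reference
ratio:

```r
h <- simulate_description_history(15000, 1900, 20, years = c(1758, 2007),
                                  seed = 3)
estimate_richness_productivity(h$series, n_boot = 2000, seed = 42)
#> Richness estimate [productivity]: 15504.62 (95%: 15355.81-15660.26)
#>   n_points: 112
#>   start_year: 1896
#>   below_observed: FALSE
extrapolate_from_reference(1107, 100, 1235)  # 11.07:1 reference ratio
#> Richness estimate [reference_ratio]: 13671.45
#>   ratio: 11.07
```

The x-intercept estimator lands within ~3% of the true total when the
record is well past its discovery peak; on a still-accelerating record
`fit_nhpp_bayes()` instead raises its `no_finite_estimate` flag rather
than reporting a spurious total.

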