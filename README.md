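# occdyn

Colonization–extinction dynamics and colonization–persistence trade-offs
in temporally sampled communities.

Microbial community surveys (16S OTU/ASV tables and the like) are
irregular time series of presences and absences: taxa appear, linger and
vanish. `occdyn` treats each taxon (or guild) as an independent two-state
Markov chain with a colonization rate *c* (per day, absent → present) and
an extinction rate *e* (present → absent), and provides the full analysis
chain around that model:

- **Rate estimation.** Exact interval transition probabilities
  P(0→1; Δt) = (c/(c+e))(1 − exp(−(c+e)Δt)),
  P(1→1; Δt) = (c + e·exp(−(c+e)Δt))/(c+e)
  make irregular sampling gaps first-class; maximum-likelihood fits per
  taxon, guild or whole community, across one or several sites/datasets.
  A dynamic-occupancy variant for replicated surveys estimates a
  per-replicate detection probability *d* alongside the rates. Taxa too
  labile to estimate (persistence *p* = 1/*e* below a quarter of the
  minimal inter-sample interval) are filtered out.
- **Model selection.** All set partitions of a site list are fitted
  (one (c, e) pair per block) and compared by AIC, Akaike weights and
  summed weight of evidence — "which lakes share one dynamics?".
- **Core/satellite structure.** A Chow structural-break scan of the
  occupancy vs log10 maximum-abundance relation yields an occupancy
  threshold: taxa above it are the community core (whose abundances are
  then checked against a lognormal rank-abundance model via
  `vegan::rad.lognormal`), the rest its satellites.
- **Trade-off tests.** Under fitness equalization every taxon shares
  k = c·p, so log *p* = log *k* − log *c*: a log–log slope of exactly
  **−1**. The package fits the OLS log–log regression with slope CIs and
  Spearman ρ, tests slope = −1, compares core vs satellite slopes
  (pooled interaction t-test), tests taxonomic coherence of strategies
  (Kruskal–Wallis on intra- vs inter-group distances in
  (log c, log p)), and supports taxon-exclusion reanalyses.
- **Synthetic data.** Generators for equalized and independent-rate
  communities, and for the crucial null: a *static* species abundance
  distribution observed through finite sequencing depth, whose apparent
  colonizations and extinctions are pure sampling artefacts.

## Worked example

Simulate one fitness-equalized community (k = 2, colonization spanning
two decades), sample it monthly for two years in four independent
campaigns, estimate per-taxon rates jointly, filter, and test the
trade-off:

```r
library(occdyn)

sims <- lapply(1:4, function(s)
  simulate_equalized(S = 200, k = 2, c_range = c(0.02, 2)/30,
                     times = seq(0, by = 30, length.out = 24),
                     site = paste0("sampling", s), seed = s, rate_seed = 99))
ps <- combine_sites(sims)
det <- Reduce(`+`, lapply(ps$sites, function(s) apply(s$detections, 1, sum)))
ps <- subset_series(ps, taxa = ps$taxa[det > 0])

fits <- fit_rates(ps)                                   # one row per taxon
flt <- filter_labile(fits[!fits$boundary, ], min_interval = 30)
tf <- loglog_tradeoff_fit(flt$kept$c, flt$kept$persistence)
tf
#> Colonization-persistence trade-off (all): n = 166
#>   log-log slope = -0.8521  (95% CI -0.9298, -0.7744; SE 0.0394)
#>   intercept K = 1.4839 (k = 4.41 under slope -1)
#>   Spearman rho = -0.8856 (p = 1.64e-56)
```

The slope is close to the equalization prediction of −1 (the residual
shrinkage toward 0 is errors-in-variables attenuation: both axes are
estimates). The first fitted rows look like:

```r
head(fits[, 1:7], 3)
#>   group       c       e    k persistence loglik n_transitions
#> 1 t0001 0.03879 0.01971 1.97        50.7  -57.4            92
#> 2 t0002 0.00194 0.00125 1.56       801.2  -16.4            92
#> 3 t0003 0.02343 0.00810 2.89       123.4  -45.6            92
```

with rates per day, persistence in days and `k = c/e` the
fitness (expected colonizations per residence time). A shell pipeline is
available too (`inst/exec/occdyn`): `simulate`, `estimate`,
`select-partitions`, `core-satellite`, `tradeoff` and `pipeline`
subcommands reading/writing the CSV trio (counts, metadata, taxonomy).

## Vignette

`vignettes/colonization-extinction-tradeoffs.Rmd` documents the model
and its assumptions, every tunable parameter, the synthetic-data
designs, numerical choices and known limitations.
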