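# hydrodiv

Does diversity in the plant traits that govern water relations — xylem
vulnerability (P50), rooting depth and profile, leaf phenology — make a
simulated tropical forest more resistant to drought?

`hydrodiv` is a desk-scale, self-contained workbench for that question. It
bundles:

* a **stochastic weather generator**: monthly climatologies scaled by
  quadratic anomaly trends, gamma-distributed daily rainfall events, and
  through-fall-exclusion drought treatments (e.g. a 50% precipitation
  reduction for 4 or 7 years);
* an **individual- and trait-based stand simulator** (daily time step, 1-ha
  stands, compiled inner loop): every tree carries an 11-trait vector,
  competes for light (height-ranked Beer–Lambert shading) and soil water
  (layered column, root-profile-weighted uptake), suffers hydraulic failure
  past the empirical 88% loss-of-conductance threshold, and — optionally —
  evolves via crossover and mutation through a seed bank;
* **functional-diversity metrics**: Gower dissimilarity with
  asymmetric-binary phenology traits, Rao's quadratic entropy (RaoQ),
  community-weighted means, trait-space PCA, k-medoids species pooling;
* the **inference layer**: a heteroscedastic Bayesian regression
  (`mu = alpha + beta*RaoQ`, `log sigma = gamma + delta*RaoQ`; adaptive
  Metropolis, bridge-sampling Bayes factors) and a linear mixed-effects
  model with AIC-guided interaction pruning, Nakagawa R², and prediction
  grids over precipitation-reduction scenarios;
* **synthetic-data generators** for every input: seasonal tropical
  climatologies, anomaly series, 96-species trait pools with a planted
  hydraulic axis (safe xylem ↔ deep roots ↔ evergreen habit), response
  tables, and continental site grids.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## A worked example

Simulate a TNF-like through-fall-exclusion experiment on a 16-species
community drawn from a synthetic pool, then ask whether pre-drought
functional diversity predicts drought biomass loss:

```r
library(hydrodiv)

pool <- synth_species_pool(96, axis_strength = 0.8, seed = 7)
cfg  <- sim_config(spinup_years = 80)   # desk-scale spin-up

man <- enumerate_diversity_design(levels = c(1, 2, 4, 8, 16, 32),
                                  replicates = 6, pool_size = 96,
                                  site = "TNF", seed = 303)
res <- run_constrained_diversity(man, pool, cfg)

dplyr::summarise(dplyr::group_by(res, richness_level),
                 raoq = mean(raoq_pre), loss = mean(bm_loss),
                 sd_loss = sd(bm_loss))
#> # A tibble: 6 x 4
#>   richness_level   raoq    loss sd_loss
#> 1              1 0       0.0193    4.59
#> 2              2 0.0706 18.3      24.6
#> 3              4 0.113  19.3      26.9
#> 4              8 0.123  -5.48      2.06
#> 5             16 0.167   3.57     11.5
#> 6             32 0.208   2.19      4.68

fit <- fit_hetero_bayes(res, response = bm_loss, diversity = raoq_pre,
                        seed = 99)
tidy(fit)       # posterior medians and 95% credible intervals
autoplot(fit)   # data + posterior mean with credible band
```

Negative `beta` means diverse communities lose less biomass on average;
negative `delta` means their losses are also less variable — both read
directly off `tidy(fit)`. In the summary above, the low-richness rows are
where catastrophic outcomes live (mean losses near 20% with spreads above
24 percentage points when an ill-suited strategy dominates), while
32-species communities sit at a few percent with a spread several times
smaller — the insurance effect of hydraulic-trait diversity acts mainly on
the *variability* of outcomes at this scale. (Losses are percentages of
pre-drought above-ground biomass; negative values are growth through the
drought.)

Continental-style analysis on a synthetic site grid:

```r
grid <- synth_continental_grid(n_sites = 150, seed = 41)
lmm  <- fit_lmm(grid)
pe   <- predict_diversity_effect(lmm, baseline = 2500,
                                 reductions = c(750, 1000, 1250))
pe$effects          # diversity effect per reduction level (30/40/50%)
plot_diversity_effect(pe)
```

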