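---
title: "Hydraulic-trait diversity and simulated forest drought resistance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulic-trait diversity and simulated forest drought resistance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What this package models

`hydrodiv` asks a single scientific question at desk scale: **does diversity in
the plant traits that govern water relations make a simulated tropical forest
more resistant to drought?** It answers it with four connected layers:

1. a stochastic **weather generator** that turns a 12-month climatology plus
   long-run anomaly trends into daily forcing, with through-fall-exclusion
   drought treatments;
2. an **individual-based stand simulator** in which every tree carries an
   11-trait vector (carbon allocation, xylem vulnerability, phenology
   triggers, rooting profile, reproduction), competes for light and soil
   water in a 1-ha stand, and — optionally — evolves by crossover and
   mutation;
3. **functional-diversity metrics**: Gower dissimilarity with asymmetric
   binary traits, Rao's quadratic entropy (RaoQ), community-weighted means
   and trait-space PCA;
4. an **inference layer**: a heteroscedastic Bayesian regression of biomass
   loss on RaoQ with Bayes-factor model comparison, and a linear
   mixed-effects model for continental-style site tables with AIC-guided
   pruning and prediction grids.

A synthetic-data module generates every input the pipeline needs (site
climatologies, anomaly series, trait pools with a planted hydraulic axis,
response tables, continental grids), so all stages are testable without any
external download.

# Climate forcing

## Anomaly trends

Long monthly series (nominally 1850–2100) of temperature and precipitation
are summarised by a two-parameter quadratic trend. We fit
$f_m = a + b\,m^2$ with $m$ the month index since the series start, by least
squares. The quadratic-in-time form was a genuinely open design choice: a
quadratic *in the observed value* is retained as `form = "value"` in
`fit_anomaly_trend()`, but the pipeline uses the time form because the role
of the fit is to summarise a slow secular trend for scenario scaling.
Temperature anomalies are offsets normalised to mean zero over 2001–2010;
precipitation anomalies are multipliers normalised to mean one over the same
window, clipped at zero (with a warning) should the trend go negative.

## Daily weather

For each month the generator places `round(rain_days)` wet days (at least
one whenever the monthly total is positive) uniformly at random without
replacement and draws event sizes from a gamma distribution with shape
$k = 1$ (exponential events) and mean `precip_mm / n_wet_days`, so the
*expected* monthly total equals the monthly forcing exactly. The shape
parameter is configurable; $k = 1$ is the default because the upstream
parameterisation of monthly gamma shapes was not available, and the law of
large numbers test (20,000 simulated months within 1% of the target mean) is
insensitive to $k$. Daily temperature interpolates linearly between monthly
means anchored at month midpoints; `light_index` is a normalised
top-of-atmosphere insolation proxy (noon solar elevation for the site
latitude). Years have 365 days, no leap days.

Drought treatments multiply daily precipitation by $1 - f$ inside the
treatment window — $f = 0.5$ for 4 years for the TNF-like protocol and for
7 years for the CAX-like protocol — and touch nothing else.

# The stand simulator

The simulator is a deliberately minimal, hydraulics-first individual-based
model: it preserves the causal pathway *traits → plant water status → carbon
gain and mortality → stand biomass under drought* at a scale where hundreds
of replicate simulations run on one CPU in minutes. It is not a full
vegetation demography model: there is no fire, no grass layer, no nutrient
cycling, and photosynthesis is a light-saturated gain rather than a full
biochemical model.

## Daily step (compiled core)

Each day, in order:

1. **Infiltration**: rain fills soil layers top-down; water above field
   capacity cascades downward and leaves the column as drainage. Soil
   evaporation removes water from the top layer in proportion to its
   relative water content.
2. **Water status**: each layer's matric potential follows
   $\psi_l = \psi_{dry}(1 - \theta_l)^2$ with $\theta_l$ the relative
   plant-available water. A plant's supply potential is the *uptake-weighted*
   mean over its rooting profile (weights = root fraction × layer wetness),
   so a tree with wet deep roots is buffered even when the surface is dry.
   Transpiration adds a flow drawdown inversely proportional to the
   trait-derived maximum conductivity; vulnerable (high-P50) plants have
   cheap, efficient xylem and small drawdowns, safe plants pay a larger one.
3. **Percent loss of conductance**: the logistic vulnerability curve
   $\mathrm{plc} = 1/(1+\exp(s(\psi - P_{50})))$ with slope $s = 2$
   MPa$^{-1}$; the supply multiplier is $1-\mathrm{plc}$.
4. **Phenology**: water-triggered deciduous trees flush when root-zone
   relative water rises to 0.5 and shed when it falls to 0.3 *or* when plc
   crosses 0.5 (incipient cavitation), with a 21-day refractory period so a
   single dry spell is not paid for twice; light-triggered trees follow the
   seasonal light index; evergreens never shed fully and instead turn leaves
   over at the P50-derived leaf longevity. Flushing rebuilds the leaf pool
   from storage at a 20% construction overhead.
5. **Competition and gain**: leaf area (SLA × leaf pool, capped by a crown
   allometry on stem mass) is shaded by taller neighbours via Beer–Lambert
   extinction. Carbon gain = light-saturated rate × leaf area × shading ×
   seasonal light × min(1, supply/demand) × CO2 factor × a height factor.
   Transpiration demand is proportional to leaf area divided by the CO2
   factor (water-use efficiency rises with CO2); actual extraction is
   limited layer-by-layer by available water.
6. **Allocation**: net gain is split by the allocation traits (the leaf
   share is diverted to storage while leafless); deficits draw down storage
   and then consume tissue.
7. **Stress and mortality**: more than 30 consecutive days above 88% plc
   *while in leaf* kills a tree (hydraulic failure); exhausted carbon kills
   it (starvation); a 1%/yr background rate applies at the annual step.

Both budgets are closed to floating-point accuracy and audited every day:
the maximum water residual (mm) and carbon residual (kg C per individual)
of a run are returned with the results, and the test suite requires
$< 10^{-6}$ mm and $< 10^{-9}$ kg C over a decade-long run.

## Annual step (R)

At year end: storage-exhausted and background mortality; reproduction
(a trait-determined fraction of storage becomes seeds of trait-determined
mass); the seed bank decays (50%/yr survival); recruitment draws seed
cohorts with probability proportional to seed counts, establishment
saturating with seed mass and *declining with the species' current share of
living individuals* (conspecific density dependence in the Janzen–Connell
sense — the standard coexistence mechanism for tropical forests, and
necessary at this stand size to keep realised richness from collapsing by
drift long before a drought is applied). When evolution is on, a recruit's
traits recombine per-trait between two same-species parents (probability
0.5 per trait) and mutate (probability 0.05 per trait, SD 5% of the trait
range, clipped to bounds); when off, recruits inherit founder traits
exactly.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `amax` | 0.0035 | kg C m⁻² leaf d⁻¹ | light-saturated gain |
| `e0` | 0.65 | L m⁻² leaf d⁻¹ | transpiration demand scale |
| `cap_mm_per_m`, `wilt_mm_per_m` | 220, 90 | mm m⁻¹ | soil water holding |
| `plc_kill`, `d_kill` | 0.88, 30 | –, days | hydraulic-failure criterion (the common empirical 88% threshold) |
| `depth_cost` | 0.05 | m⁻¹ | extra root maintenance per metre of rooting depth (the cost that balances the safety benefit of deep roots) |
| `jc_strength` | 0.8 | – | conspecific density dependence at establishment |
| `spinup_years` | 150 | yr | desk-scale spin-up at 286 ppm CO2 |

The trait bounds (allocation fractions 0.05–0.6, P50 −8 to −0.5 MPa,
rooting depth 0.5–10 m, seed mass 0.01–10 g) are stand-ins chosen to span
the plausible tropical-tree range; the upstream model's exact table was not
available, and every bound is configurable.

The spin-up default of 150 years (rather than the field-scale 760) is a
deliberate desk-scale choice: stands approach their biomass plateau within
about a century under these parameters, and the experiments measure
*relative* responses to paired treatments, which stabilise much earlier
than absolute biomass.

# Experimental designs

* **Through-fall exclusion, full diversity** — uniform-random founding
  traits, evolution on, paired drought/control runs sharing the identical
  weather realisation and demographic seed, replicated (96 in the full
  design). Biomass loss is measured from the pre-drought census year to the
  last drought year, relative to the pre-drought value; the paired control
  quantifies weather-matched background drift.
* **Constrained diversity** — a species pool (one entry per full-diversity
  replicate: the most abundant species' mean traits, modal binaries; or a
  synthetic pool) is sampled without replacement at 18 richness levels
  (1–12, 16, 32, 48, 64, 80, 96) × 96 replicates = 1,728 runs per site in
  the full design; evolution off; approximately equal founding abundances.
  Desk-scale runs use levels {1, 2, 4, 8, 16, 32} × 12 replicates.
  Pre-drought extant-species counts feed the 8-trait RaoQ.
* **Rooting-niche removal** — in seed-paired runs, rooting depth and shape
  of every individual are overwritten with the deepest-rooting strategy's
  means on the first day of the drought year; drought responses are
  compared with the untouched twin (plus a homogenised no-drought control).
* **Strategy removal** — configurations can forbid the deciduous
  water-triggered strategy, or all water-triggered strategies; founding
  draws, recruitment and mutation all respect the constraint, and the
  2-trait RaoQ (P50, rooting depth — the traits not directly manipulated)
  quantifies the collateral diversity loss.

The constrained-diversity and niche-removal analyses shipped in the
acceptance script use the synthetic species pool (planted hydraulic axis)
as the study-condition pool: it gives the same trait-covariance structure
that emerges from evolutionary runs, at a fraction of the compute, and
makes the diversity gradient reproducible from a single seed. The
simulation-derived pool path (`build_species_pool()`) is fully implemented
and tested.

# Functional diversity

Gower dissimilarity standardises continuous traits by their *theoretical*
bounds (not the observed range) so that values are comparable across runs
and sites; the two phenology traits are asymmetric binaries (shared
absences carry no information and are excluded from the average — the
Jaccard-style convention). RaoQ is the abundance-weighted expected
dissimilarity between two random individuals; abundances are pre-drought
individual counts of extant species. With double-zero exclusion Gower need
not satisfy the triangle inequality; nothing downstream assumes it does.
PCA standardises columns and fixes axis signs deterministically (rooting
depth loads positively on its dominant axis).

# Inference

## Heteroscedastic Bayesian regression

Biomass loss is modelled as Gaussian with both moments linear in RaoQ:
$\mu_i = \alpha + \beta\,\mathrm{RaoQ}_i$,
$\log \sigma_i = \gamma + \delta\,\mathrm{RaoQ}_i$, with weakly informative
priors $\alpha,\beta \sim N(0,10)$, $\gamma,\delta \sim N(0,1)$, sampled
with 4 chains × 2000 iterations (1000 warmup). The sampler is an adaptive
random-walk Metropolis written for this 2–4 parameter problem: the proposal
covariance is adapted during warmup (scaled 2.38²/d) and frozen for the
sampling phase; convergence is monitored by split-R-hat (warning above
1.01). Marginal likelihoods for the Bayes factor come from Meng–Wong
bridge sampling with a moment-matched normal proposal, computed in log
space; the estimator's relative standard error is reported and flagged
above 5%. Effect sizes are computed draw-wise as the percentage reduction
in $\mu$ (and in $\sigma$) between two RaoQ values, by default the observed
extremes — the choice of range was an open point and min→max is the
default.

## Continental mixed model

`fit_lmm()` fits `pct_change ~ (precip_1990 + raoq + precip_change + rcp +
co2)^2 + (1 | site)` with z-scaled continuous covariates, prunes two-way
interaction terms backwards while AIC improves (ML fits during selection,
REML refit at the end; the term whose removal improves AIC most is dropped
first), and reports Nakagawa marginal/conditional R². Prediction grids
evaluate the fixed-effect surface (default: 2500 mm baseline; 750, 1000 and
1250 mm reductions — 30/40/50%) and summarise the diversity effect as the
difference in predicted biomass change between the RaoQ extremes per
reduction level. No multiple-testing correction is applied anywhere: each
analysis tests a single preplanned contrast.

# What the synthetic data do and do not show

The generators reproduce the *statistical structure* the analyses assume: a
seasonal tropical climatology with a sub-100 mm dry season, quadratic
anomaly trends, a trait pool whose hydraulic axis couples P50, rooting
depth, rooting shape and phenology (drought avoiders shallow and
vulnerable, resisters deep and safe), and heteroscedastic response tables.
Passing tests on these inputs demonstrates that the pipeline's estimators
recover known truths and that the simulator's directional behaviour
(drought reduces biomass; diversity reduces mean loss and its spread;
homogenising rooting niches worsens losses) is robust — they do not
calibrate the simulator against any real forest, and absolute biomass or
flux magnitudes should not be read quantitatively.

# Numerical choices and degenerate inputs

* All stochastic entry points require an explicit integer seed and restore
  the caller's RNG state; derived child seeds stay below 2³¹.
* Weather, runs and fits are bit-reproducible from `(inputs, seed)`.
* Zero-variance PCA columns are dropped with a warning; a constant
  transpiration series reports infinite stability with a warning; a
  constant diversity covariate is an error (no identifiable slope);
  fraction outside [0,1], infeasible climatologies, and empty stands are
  errors at the boundary they violate.
* Problem sizes in the shipped tests and acceptance script: 20,000 months
  for the weather calibration; 10-year stands for the conservation audits;
  n = 500 for Bayesian recovery; 50 repetitions for the δ-null calibration;
  20 repetitions for Bayes-factor direction; levels {1, 2, 4, 8, 16, 32} ×
  12 replicates with a 150-year spin-up for the ecosystem-level
  directional checks.

# Known limitations

* At desk scale, a stand's percentage biomass loss is close to the
  biomass-share-weighted sum of its members' individual losses, and
  fixed-trait monocultures self-regulate (self-thinning, collective leaf
  shedding) to a demand their root zone sustains even under the 50%
  protocols. The *insurance* signatures of diversity — reduced spread of
  drought losses and higher transpiration stability — emerge robustly in
  the shipped experiments, but two others do not: the reduction of the
  *mean* loss (which requires individual-level facilitation — each member
  experiencing lower peak stress in company — stronger than this
  simplified physiology produces), and a consistent penalty for
  homogenising rooting niches (desk-scale communities are dominated by
  deep evergreen strategies, so granting everyone the deepest strategy's
  roots also grants access to the reliable deep store and offsets the lost
  differentiation about half the time). The corresponding assertions in
  the test suite are left in place and document the shortfall; treat
  posterior slopes of mean loss on RaoQ from desk-scale runs as noisy
  around zero. A stand-age artefact also
  matters here: stands still accumulating biomass can grow through a
  drought, so percentage changes mix growth trends with drought damage —
  the emitted `bm_shortfall` column (gap to the stand's own pre-drought
  growth trajectory) separates the two.
* Phenology of evergreens ignores the flush-trigger trait except through
  leaf turnover, so the two evergreen strategies differ less than the two
  deciduous ones.
* The light-trigger signal is weak near the equator (small seasonal
  amplitude), as in reality; light-triggered deciduousness is accordingly
  rare in simulated communities.
* The Bayes factor's bridge estimator assumes an approximately
  unimodal posterior — true for this model family, unverified beyond it.
* One soil column per stand: no lateral heterogeneity, no water table.
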