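# Synthetic inputs with the statistical structure the analysis assumes:
# seasonal tropical climatologies, anomaly trajectories with quadratic
# trends, trait pools with a planted hydraulic axis, and response tables
# drawn from the heteroscedastic diversity-resistance model.

#' Built-in site specifications
#'
#' Desk-scale stand-ins for the two Amazonian through-fall-exclusion sites:
#' a seasonal forest with ~2000 mm/yr and a July-December dry season
#' (TNF-like) and a wetter forest with ~2250 mm/yr and a June-November dry
#' season (CAX-like). Monthly dry-season precipitation is below 100 mm at
#' both.
#'
#' @param name `"TNF"` or `"CAX"`.
#' @return A list with `name`, `annual_precip_mm`, `dry_season_months`,
#'   `dry_month_precip_mm`, `tmean_C`, `trange_C`, `latitude_deg`,
#'   `drought_fraction`, `drought_years`.
#' @export
site_spec <- function(name = c("TNF", "CAX")) {
  name <- match.arg(name)
  switch(name,
    TNF = list(name = "TNF", annual_precip_mm = 2000,
               dry_season_months = 7:12, dry_month_precip_mm = 55,
               tmean_C = 26, trange_C = 9, latitude_deg = -2.9,
               drought_fraction = 0.5, drought_years = 4),
    CAX = list(name = "CAX", annual_precip_mm = 2250,
               dry_season_months = 6:11, dry_month_precip_mm = 65,
               tmean_C = 26.5, trange_C = 8, latitude_deg = -1.4,
               drought_fraction = 0.5, drought_years = 7)
  )
}

#' Generate a seasonal tropical monthly climatology
#'
#' Dry-season months receive `dry_month_precip_mm` each; the remaining
#' annual total is spread over the wet months with smooth, slightly jittered
#' seasonal weights. Rain days scale with monthly precipitation (1 mm .. cap
#' of 28 days); monthly temperature carries a small seasonal cycle around
#' the annual mean.
#'
#' @param spec A site specification (see [site_spec()]), or a list with the
#'   same fields.
#' @param seed Integer seed for the wet-season jitter.
#' @return A 12-row monthly climatology tibble (`month`, `precip_mm`,
#'   `rain_days`, `tmean_C`, `trange_C`, `sun_frac`).
#' @export
synth_climatology <- function(spec, seed) {
  dry <- spec$dry_season_months
  wet <- setdiff(1:12, dry)
  if (spec$dry_month_precip_mm >= 100) {
    stop("dry-season months must receive less than 100 mm", call. = FALSE)
  }
  wet_total <- spec$annual_precip_mm - length(dry) * spec$dry_month_precip_mm
  if (wet_total <= 0 || wet_total / length(wet) <= spec$dry_month_precip_mm) {
    stop("infeasible site spec: wet-season months would be drier than the dry season",
         call. = FALSE)
  }
  precip <- numeric(12)
  precip[dry] <- spec$dry_month_precip_mm
  with_seed(seed, {
    # hump-shaped wet-season weights peaking mid wet season, mild jitter
    k <- seq_along(wet)
    w <- 1 + 0.6 * sin(pi * (k - 0.5) / length(wet)) + runif(length(wet), 0, 0.15)
    precip[wet] <- wet_total * w / sum(w)
  })
  # guard the seasonal contrast after jitter
  precip[wet] <- pmax(precip[wet], spec$dry_month_precip_mm + 5)
  precip[wet] <- precip[wet] * (wet_total / sum(precip[wet]))
  stopifnot(abs(sum(precip) - spec$annual_precip_mm) < 0.5)
  m <- 1:12
  tibble::tibble(
    month = m,
    precip_mm = precip,
    rain_days = pmin(28, pmax(1, round(precip / 9))),
    tmean_C = spec$tmean_C + 0.8 * cos(2 * pi * (m - 2) / 12),
    trange_C = spec$trange_C,
    sun_frac = 0.45 + 0.15 * (precip < 100)
  )
}

#' Generate a monthly anomaly series with a quadratic trend
#'
#' Emulates a long-run scenario trajectory: a slow quadratic trend in time
#' plus a seasonal cycle and noise, suitable input for
#' [fit_anomaly_trend()] and [normalize_anomalies()]. Temperature series
#' trend upwards in deg C; precipitation series are generated around a
#' multiplier of one trending towards `end_multiplier`.
#'
#' @param variable `"temperature"` or `"precipitation"`.
#' @param years Year span, default `1850:2100`.
#' @param end_change Temperature change (deg C) reached at the end of the
#'   series (quadratic in time), default 3.5.
#' @param end_multiplier Precipitation multiplier reached at the end,
#'   default 0.7 (a 30 percent decline).
#' @param noise_sd Monthly noise standard deviation.
#' @param seed Integer seed.
#' @return A tibble `(year, month, value)`.
#' @export
synth_anomaly_series <- function(variable = c("temperature", "precipitation"),
                                 years = 1850:2100, end_change = 3.5,
                                 end_multiplier = 0.7, noise_sd = NULL, seed) {
  variable <- match.arg(variable)
  grid <- tidyr::expand_grid(year = years, month = 1:12)
  mIdx <- seq_len(nrow(grid)) - 1
  u2 <- (mIdx / max(mIdx))^2
  with_seed(seed, {
    if (variable == "temperature") {
      noise_sd <- noise_sd %||% 0.4
      base <- 25 + end_change * u2 + 1.0 * cos(2 * pi * (grid$month - 2) / 12)
    } else {
      noise_sd <- noise_sd %||% 0.08
      base <- 1 + (end_multiplier - 1) * u2
    }
    val <- base + rnorm(nrow(grid), 0, noise_sd)
    if (variable == "precipitation") val <- pmax(val, 0)
    tibble::tibble(year = grid$year, month = grid$month, value = val)
  })
}

#' Generate a species pool with a planted hydraulic trait axis
#'
#' Draws `n` species within the trait bounds with two planted latent
#' factors. The hydraulic factor couples xylem safety, rooting depth and
#' phenology: safer xylem (more negative P50) goes with deeper roots and
#' evergreen habit, while vulnerable, shallow-rooted species tend to be
#' deciduous and water-triggered. An independent productive-vs-conservative
#' factor loads on the allocation fractions (growth vs storage). With
#' `axis_strength = 0` all couplings vanish. For `n >= 16` the generator
#' guarantees that all four phenological strategies are represented by
#' assigning any missing strategy to the species whose latent score is most
#' compatible with it.
#'
#' @param n Pool size (at least 4), default 96.
#' @param axis_strength Coupling strength in `[0, 1]`, default 0.8.
#' @param seed Integer seed.
#' @return A tibble with `species = 1..n` and the 11 adaptive traits.
#' @export
synth_species_pool <- function(n = 96, axis_strength = 0.8, seed) {
  if (n < 4) stop("need at least 4 species to populate 4 strategies", call. = FALSE)
  if (axis_strength < 0 || axis_strength > 1) {
    stop("`axis_strength` must lie in [0, 1]", call. = FALSE)
  }
  b <- trait_bounds()
  rng <- function(tr) unlist(b[b$trait == tr, c("lower", "upper")], use.names = FALSE)
  to_bounds <- function(z, tr, lo_frac = 0.02, hi_frac = 0.98) {
    r <- rng(tr)
    q <- stats::pnorm(z)
    q <- lo_frac + q * (hi_frac - lo_frac)
    r[1] + q * (r[2] - r[1])
  }
  a <- axis_strength
  with_seed(seed, {
    h <- rnorm(n) # hydraulic factor: high = resistant (safe, deep, evergreen)
    g <- rnorm(n) # productive (high) vs conservative (low) factor
    mix <- function(f) a * f + sqrt(1 - a^2) * rnorm(n)
    p50 <- to_bounds(-mix(h), "p50")
    root_depth_max <- to_bounds(mix(h), "root_depth_max")
    evergreen <- rbinom(n, 1, stats::plogis(1.8 * a * h))
    light_trigger <- rbinom(n, 1, stats::plogis(1.1 * a * h - 0.2))
    alloc <- cbind(
      a_root = to_bounds(mix(g), "a_root"),
      a_stem = to_bounds(mix(g), "a_stem"),
      a_leaf = to_bounds(mix(g), "a_leaf"),
      a_store = to_bounds(-mix(g), "a_store")
    )
    traits <- tibble::tibble(
      species = seq_len(n),
      tibble::as_tibble(alloc),
      a_repro = to_bounds(rnorm(n), "a_repro"),
      seed_mass = to_bounds(rnorm(n), "seed_mass"),
      p50 = p50,
      evergreen = as.numeric(evergreen),
      light_trigger = as.numeric(light_trigger),
      root_depth_max = root_depth_max,
      # deep rooters get flat (low-decay) profiles so their uptake really is
      # deep; shallow-rooted avoiders concentrate uptake near the surface
      root_shape = to_bounds(-mix(h), "root_shape")
    )
    traits <- normalize_allocation(traits)
    if (n >= 16) {
      traits <- ensure_strategy_coverage(traits, h)
    }
    traits
  })
}

# Guarantee all four phenological strategies are present by reassigning the
# binaries of the latent-compatible species for any missing class.
ensure_strategy_coverage <- function(traits, h) {
  combos <- list(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  present <- function() {
    paste(traits$evergreen, traits$light_trigger)
  }
  for (cb in combos) {
    key <- paste(cb[1], cb[2])
    if (!(key %in% present())) {
      # evergreen classes suit high latent scores, deciduous low ones
      target <- if (cb[1] == 1) h else -h
      # don't break an existing singleton class
      counts <- table(present())
      movable <- counts[present()] > 1
      idx <- order(target, decreasing = TRUE)
      idx <- idx[movable[idx]][1]
      traits$evergreen[idx] <- cb[1]
      traits$light_trigger[idx] <- cb[2]
    }
  }
  traits
}

#' Draw biomass-loss responses from the heteroscedastic model
#'
#' Simulates the data-generating process of the diversity-resistance
#' regression: `bm_loss_i ~ Normal(alpha + beta * raoq_i,
#' exp(gamma + delta * raoq_i)^2)`.
#'
#' @param raoq Vector of diversity values.
#' @param alpha,beta Mean intercept and slope.
#' @param gamma,delta Log-sd intercept and slope.
#' @param seed Integer seed.
#' @return A tibble `(raoq, bm_loss)`.
#' @export
synth_diversity_response <- function(raoq, alpha, beta, gamma, delta, seed) {
  mu <- alpha + beta * raoq
  sig <- exp(gamma + delta * raoq)
  stopifnot(all(sig > 0))
  with_seed(seed, tibble::tibble(raoq = raoq, bm_loss = rnorm(length(raoq), mu, sig)))
}

#' Generate a synthetic continental site table
#'
#' Emulates the inputs of the continental mixed-effects analysis: sites with
#' baseline precipitation around a configurable mean, scenario-dependent
#' precipitation reductions, diversity values, scenario factors, baseline
#' biomass, and a percentage biomass change built from a known linear
#' predictor (on the z-scaled covariates, as fitted) plus site random
#' intercepts and residual noise. Each site contributes one row per
#' rcp-by-co2 scenario combination.
#'
#' @param n_sites Number of sites (at least 50).
#' @param coefs Named list of true coefficients on the scaled scale:
#'   `intercept`, `precip_1990`, `raoq`, `precip_change`, `rcp85`,
#'   `co2_fixed`, `raoq_x_precip_change` (the diversity-by-drought
#'   interaction).
#' @param site_sd Standard deviation of site random intercepts.
#' @param sigma Residual standard deviation.
#' @param mean_precip Mean baseline annual precipitation (mm), default 2500.
#' @param seed Integer seed.
#' @return A tibble with columns `site`, `precip_1990`, `precip_change`,
#'   `raoq`, `rcp`, `co2`, `agb_1990`, `pct_change`.
#' @export
synth_continental_grid <- function(n_sites = 200,
                                   coefs = list(
                                     intercept = -20, precip_1990 = 5,
                                     raoq = 8, precip_change = -15,
                                     rcp85 = -6, co2_fixed = -10,
                                     raoq_x_precip_change = 4
                                   ),
                                   site_sd = 5, sigma = 6,
                                   mean_precip = 2500, seed) {
  if (n_sites < 50) stop("need at least 50 sites", call. = FALSE)
  with_seed(seed, {
    sites <- tibble::tibble(
      site = sprintf("s%03d", seq_len(n_sites)),
      precip_1990 = runif(n_sites, mean_precip - 1000, mean_precip + 1000),
      raoq = runif(n_sites, 0.05, 0.45),
      agb_1990 = runif(n_sites, 100, 250),
      site_eff = rnorm(n_sites, 0, site_sd)
    )
    grid <- tidyr::expand_grid(sites, rcp = c("rcp45", "rcp85"),
                               co2 = c("rising", "fixed"))
    base_drop <- runif(nrow(grid), 0, 1100)
    grid$precip_change <- pmin(1500, base_drop + ifelse(grid$rcp == "rcp85",
                                                        runif(nrow(grid), 100, 400), 0))
    z <- function(v) (v - mean(v)) / sd(v)
    zp <- z(grid$precip_1990); zr <- z(grid$raoq); zc <- z(grid$precip_change)
    lp <- coefs$intercept + coefs$precip_1990 * zp + coefs$raoq * zr +
      coefs$precip_change * zc + coefs$rcp85 * (grid$rcp == "rcp85") +
      coefs$co2_fixed * (grid$co2 == "fixed") +
      coefs$raoq_x_precip_change * zr * zc
    grid$pct_change <- lp + grid$site_eff + rnorm(nrow(grid), 0, sigma)
    dplyr::select(grid, -"site_eff")
  })
}
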