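# Experimental designs: through-fall-exclusion drought with full diversity,
# the constrained-diversity series, rooting-niche removal, and strategy
# removal.

#' Assemble the forcing for a site-scale drought experiment
#'
#' Builds the multi-year daily weather for one run: spin-up years at
#' pre-industrial CO2, then ambient-CO2 years, with an optional
#' through-fall-exclusion treatment (a fixed fractional reduction of daily
#' precipitation over the drought window).
#'
#' @param site `"TNF"` or `"CAX"` (see [site_spec()]), or a site spec list.
#' @param cfg A [sim_config()]; `spinup_years`, `co2_spinup`, `co2_ambient`
#'   are honoured.
#' @param pre_years,post_years Ambient-CO2 years before/after the drought
#'   window.
#' @param drought If `TRUE`, apply the site's protocol (fraction and
#'   duration from the spec) starting after `pre_years`.
#' @param seed Integer seed for the weather realisation.
#' @param clim_seed Seed of the site climatology (fixed by default so every
#'   run of a site shares one climatology).
#' @return A list: `weather` (daily tibble), `drought_start`,
#'   `drought_years`, `pre_census_year`, `end_year`, `n_years`.
#' @export
experiment_forcing <- function(site, cfg = sim_config(), pre_years = 10,
                               post_years = 3, drought = FALSE, seed,
                               clim_seed = 101) {
  spec <- if (is.character(site)) site_spec(site) else site
  clim <- synth_climatology(spec, seed = clim_seed)
  drought_start <- cfg$spinup_years + pre_years + 1
  n_years <- cfg$spinup_years + pre_years + spec$drought_years + post_years
  co2_path <- tibble::tibble(
    year = seq_len(n_years),
    co2_ppm = ifelse(year <= cfg$spinup_years, cfg$co2_spinup, cfg$co2_ambient)
  )
  weather <- generate_daily_weather(clim, seed = seed,
                                    latitude_deg = spec$latitude_deg,
                                    co2_ppm = co2_path, years = seq_len(n_years))
  if (drought) {
    weather <- apply_drought(weather, drought_start, spec$drought_years,
                             spec$drought_fraction)
  }
  list(weather = weather, drought_start = drought_start,
       drought_years = spec$drought_years,
       pre_census_year = drought_start - 1,
       end_year = drought_start + spec$drought_years - 1,
       n_years = n_years)
}

# Percentage AGB loss between the pre-drought census year and the last
# drought year (positive = loss).
bm_loss_from_annual <- function(annual, pre_year, end_year) {
  pre <- annual$agb_t_ha[annual$year == pre_year]
  post <- annual$agb_t_ha[annual$year == end_year]
  if (length(pre) == 0 || length(post) == 0 || pre <= 0) return(NA_real_)
  100 * (pre - post) / pre
}

# Drought-attributable biomass shortfall: the gap between the end-of-drought
# biomass and the biomass expected had the stand continued on its own
# pre-drought growth trajectory (geometric-mean growth over the five years
# before the treatment), as a percentage of pre-drought biomass.
bm_shortfall_from_annual <- function(annual, pre_year, end_year) {
  pre <- annual$agb_t_ha[annual$year == pre_year]
  base <- annual$agb_t_ha[annual$year == pre_year - 5]
  post <- annual$agb_t_ha[annual$year == end_year]
  if (length(pre) == 0 || length(post) == 0 || length(base) == 0 ||
      pre <= 0 || base <= 0) {
    return(NA_real_)
  }
  g <- (pre / base)^(1 / 5) - 1
  g <- min(max(g, -0.1), 0.1) # clamp implausible trend extrapolations
  expected <- pre * (1 + g)^(end_year - pre_year)
  100 * (expected - post) / pre
}

#' Run the through-fall-exclusion experiment with full diversity
#'
#' For each replicate: a fresh uniform-random founding community with
#' evolution on, and a weather-matched pair of runs (control and drought
#' sharing the identical weather realisation and demographic seed), the
#' drought run with the site's protocol (50 percent daily precipitation
#' reduction for 4 years at the TNF-like site, 7 at the CAX-like site).
#'
#' @param site `"TNF"` or `"CAX"`.
#' @param n_replicates Number of replicates (at least 2; the full design
#'   uses 96).
#' @param cfg A [sim_config()].
#' @param seed Master seed; replicate seeds derive from it.
#' @param keep_census If `TRUE` (default), keep each replicate's pre-drought
#'   census (needed by [build_species_pool()]).
#' @return A tibble of class `throughfall_results`: one row per replicate
#'   with `bm_loss` (drought) and `bm_loss_control`, pre-drought AGB and
#'   strategy shares, and (optionally) a `census` list-column.
#' @export
run_throughfall_experiment <- function(site, n_replicates = 96,
                                       cfg = sim_config(), seed,
                                       keep_census = TRUE) {
  if (n_replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  seeds <- matrix(seed_stream(seed, 2 * n_replicates), ncol = 2)
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    fc_c <- experiment_forcing(site, cfg, drought = FALSE, seed = seeds[r, 1])
    fc_d <- experiment_forcing(site, cfg, drought = TRUE, seed = seeds[r, 1])
    run_c <- run_stand(fc_c$weather, cfg = cfg, seed = seeds[r, 2],
                       census_years = fc_c$pre_census_year)
    run_d <- run_stand(fc_d$weather, cfg = cfg, seed = seeds[r, 2],
                       census_years = fc_d$pre_census_year)
    pre <- run_d$annual[run_d$annual$year == fc_d$pre_census_year, ]
    out <- tibble::tibble(
      replicate = r,
      site = if (is.character(site)) site else site$name,
      bm_loss = bm_loss_from_annual(run_d$annual, fc_d$pre_census_year, fc_d$end_year),
      bm_loss_control = bm_loss_from_annual(run_c$annual, fc_c$pre_census_year, fc_c$end_year),
      agb_pre = pre$agb_t_ha,
      n_pre = pre$n_individuals
    )
    if (keep_census) {
      out$census <- list(run_d$censuses[[as.character(fc_d$pre_census_year)]])
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("throughfall_results", class(out))
  out
}

#' Build a species pool from full-diversity replicates
#'
#' One pool entry per replicate: the most abundant extant species in that
#' replicate's pre-drought census (most individuals; ties broken by total
#' above-ground biomass), recorded as the mean trait vector over its
#' individuals, with the binary traits taking their modal value.
#'
#' @param results A `throughfall_results` tibble with a `census` list-column
#'   (or any tibble with one census per row in `census`).
#' @param pool_size Number of pool entries required (replicates beyond this
#'   are ignored; fewer contributing replicates is an error).
#' @return A species-pool tibble (`species = 1..pool_size` + trait columns).
#' @export
build_species_pool <- function(results, pool_size = 96) {
  stopifnot("census" %in% names(results))
  entries <- purrr::map(results$census, function(cs) {
    if (is.null(cs) || nrow(cs) == 0) return(NULL)
    ab <- dplyr::summarise(dplyr::group_by(cs, .data$species),
                           n = dplyr::n(), agb = sum(.data$agb_kg),
                           .groups = "drop")
    ab <- dplyr::arrange(ab, dplyr::desc(.data$n), dplyr::desc(.data$agb))
    top <- cs[cs$species == ab$species[1], , drop = FALSE]
    b <- trait_bounds()
    tr <- lapply(b$trait, function(nm) {
      v <- top[[nm]]
      if (b$kind[b$trait == nm] == "asymm") {
        as.numeric(mean(v) >= 0.5)
      } else {
        mean(v)
      }
    })
    names(tr) <- b$trait
    tibble::as_tibble(tr)
  })
  keep <- !vapply(entries, is.null, logical(1))
  if (any(!keep)) {
    warning(sprintf("%d replicate(s) with zero survivors skipped", sum(!keep)))
  }
  entries <- entries[keep]
  if (length(entries) < pool_size) {
    stop(sprintf("only %d contributing replicates for pool of %d",
                 length(entries), pool_size), call. = FALSE)
  }
  pool <- dplyr::bind_rows(entries[seq_len(pool_size)])
  pool <- normalize_allocation(pool)
  dplyr::bind_cols(tibble::tibble(species = seq_len(pool_size)), pool)
}

#' Enumerate the constrained-diversity design
#'
#' One manifest row per (richness level, replicate); each row draws its
#' species without replacement from the pool, with evolution off and
#' approximately equal initial abundances. The full published design (18
#' richness levels of 1-12, 16, 32, 48, 64, 80, 96 species, replicated 96
#' times) yields 1728 rows per site.
#'
#' @param levels Richness levels; default `c(1:12, 16, 32, 48, 64, 80, 96)`.
#' @param replicates Replicates per level; default 96.
#' @param pool_size Size of the species pool drawn from; default 96.
#' @param site Site label recorded in the manifest.
#' @param seed Master seed; per-run species draws and run seeds derive from
#'   it.
#' @return A manifest tibble: `run_id`, `site`, `richness_level`,
#'   `replicate`, `seed`, `treatment`, `diversity_treatment`, `species`
#'   (list-column of pool ids).
#' @export
enumerate_diversity_design <- function(levels = c(1:12, 16, 32, 48, 64, 80, 96),
                                       replicates = 96, pool_size = 96,
                                       site = "TNF", seed) {
  if (any(levels > pool_size)) {
    stop("richness level exceeds the pool size", call. = FALSE)
  }
  grid <- tidyr::expand_grid(richness_level = levels,
                             replicate = seq_len(replicates))
  seeds <- seed_stream(seed, 2 * nrow(grid))
  draw_seeds <- seeds[seq_len(nrow(grid))]
  run_seeds <- seeds[nrow(grid) + seq_len(nrow(grid))]
  grid$species <- purrr::map2(grid$richness_level, draw_seeds, function(k, s) {
    with_seed(s, sort(sample.int(pool_size, k)))
  })
  tibble::tibble(
    run_id = sprintf("%s_L%02d_R%02d", site, grid$richness_level, grid$replicate),
    site = site,
    richness_level = grid$richness_level,
    replicate = grid$replicate,
    seed = run_seeds,
    treatment = "drought",
    diversity_treatment = "constrained",
    species = grid$species
  )
}

# Founding trait table for a constrained run: pool species replicated to
# approximately equal initial abundance.
constrained_founders <- function(pool, species_ids, n_init) {
  k <- length(species_ids)
  per <- rep(n_init %/% k, k)
  extra <- n_init %% k
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  idx <- rep(match(species_ids, pool$species), times = per)
  pool[idx, , drop = FALSE]
}

#' Run the constrained-diversity experiment
#'
#' Executes every manifest row: fixed-trait simulation (evolution off) under
#' the site's drought protocol, recording pre-drought functional diversity
#' (8-trait RaoQ over extant-species abundances), percentage biomass loss
#' over the drought window, transpiration statistics, and pre-drought
#' strategy shares. Runs extinct before the drought are flagged and carry
#' `NA` responses.
#'
#' @param manifest From [enumerate_diversity_design()].
#' @param pool Species pool tibble (see [build_species_pool()] or
#'   [synth_species_pool()]).
#' @param cfg A [sim_config()] (`evolution` is forced off).
#' @param pre_years,post_years Window layout (see [experiment_forcing()]).
#' @return A results tibble: manifest fields plus `raoq_pre`, `bm_loss`,
#'   `transp_mean`, `transp_sd`, `transp_stability`, strategy shares, and
#'   `extinct_pre_drought`.
#' @export
run_constrained_diversity <- function(manifest, pool, cfg = sim_config(),
                                      pre_years = 10, post_years = 3) {
  cfg$evolution <- FALSE
  d8 <- gower_dissimilarity(pool[c("species", FD_TRAITS_8)])
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    mrow <- manifest[i, ]
    ss <- seed_stream(mrow$seed, 2)
    fc <- experiment_forcing(mrow$site, cfg, pre_years = pre_years,
                             post_years = post_years, drought = TRUE,
                             seed = ss[1])
    founders <- constrained_founders(pool, mrow$species[[1]], cfg$n_init)
    run <- run_stand(fc$weather, traits = founders, cfg = cfg, seed = ss[2],
                     census_years = fc$pre_census_year)
    census <- run$censuses[[as.character(fc$pre_census_year)]]
    pre <- run$annual[run$annual$year == fc$pre_census_year, ]
    extinct <- is.null(census) || nrow(census) == 0
    raoq_pre <- NA_real_
    if (!extinct) {
      ab <- census_abundance(census)
      p <- setNames(rep(0, nrow(pool)), pool$species)
      p[as.character(ab$species)] <- ab$abundance
      raoq_pre <- rao_q(d8, p)
    }
    window <- run$annual[run$annual$year >= fc$pre_census_year - 5, ]
    ts <- if (nrow(window) >= 2 && sd(window$transpiration_mm) > 0) {
      transpiration_stability(window$transpiration_mm)
    } else {
      tibble::tibble(mean = NA_real_, sd = NA_real_, stability = NA_real_)
    }
    tibble::tibble(
      mrow[c("run_id", "site", "richness_level", "replicate", "seed",
             "treatment", "diversity_treatment")],
      raoq_pre = raoq_pre,
      bm_loss = if (extinct) NA_real_ else
        bm_loss_from_annual(run$annual, fc$pre_census_year, fc$end_year),
      bm_shortfall = if (extinct) NA_real_ else
        bm_shortfall_from_annual(run$annual, fc$pre_census_year, fc$end_year),
      transp_mean = ts$mean, transp_sd = ts$sd, transp_stability = ts$stability,
      Evergreen_Light = pre$Evergreen_Light,
      Evergreen_Water = pre$Evergreen_Water,
      Deciduous_Light = pre$Deciduous_Light,
      Deciduous_Water = pre$Deciduous_Water,
      extinct_pre_drought = extinct
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$extinct_pre_drought)) {
    message(sprintf("%d run(s) extinct before drought; excluded from regressions",
                    sum(out$extinct_pre_drought)))
  }
  out
}

#' Select the replicate with the most even strategy composition
#'
#' Among runs in which all four phenological strategies are present and the
#' least abundant strategy holds at least `min_share` of biomass, returns
#' the run maximising Pielou evenness of the four shares (ties broken by
#' `run_id`).
#'
#' @param results A results tibble with the four strategy-share columns.
#' @param min_share Minimum biomass share of the rarest strategy (default
#'   0.2).
#' @return The selected `run_id` (scalar character).
#' @export
select_even_replicate <- function(results, min_share = 0.2) {
  shares <- as.matrix(results[levels(classify_strategy(1, 1))])
  minsh <- apply(shares, 1, min)
  ok <- minsh >= min_share
  if (!any(ok)) {
    stop("no run has all four strategies at >= the minimum share; enlarge the design",
         call. = FALSE)
  }
  pielou <- apply(shares[ok, , drop = FALSE], 1, function(s) {
    s <- s[s > 0]
    -sum(s * log(s)) / log(4)
  })
  cand <- results$run_id[ok]
  cand[order(-pielou, cand)][1]
}

#' Remove rooting-niche differentiation from a stand
#'
#' Overwrites every individual's `root_depth_max` and `root_shape` with the
#' mean values of the reference strategy (by default the deepest-rooting
#' strategy present), leaving all other traits untouched. This removes
#' below-ground niche differentiation while preserving above-ground
#' variation.
#'
#' @param stand A `stand` object with at least one living individual.
#' @param reference `"deepest"` (default) or one of the four strategy
#'   labels.
#' @return The modified stand.
#' @export
remove_root_niche <- function(stand, reference = "deepest") {
  alive <- stand$state[, "alive"] > 0.5
  if (!any(alive)) stop("stand is empty", call. = FALSE)
  tr <- stand$traits[alive, ]
  strat <- classify_strategy(tr$evergreen, tr$light_trigger)
  depth_by <- tapply(tr$root_depth_max, strat, mean)
  shape_by <- tapply(tr$root_shape, strat, mean)
  ref <- if (identical(reference, "deepest")) {
    names(which.max(depth_by))
  } else {
    if (!(reference %in% names(depth_by)) || is.na(depth_by[reference])) {
      stop("reference strategy not present in the stand", call. = FALSE)
    }
    reference
  }
  stand$traits$root_depth_max <- rep(unname(depth_by[ref]), nrow(stand$traits))
  stand$traits$root_shape <- rep(unname(shape_by[ref]), nrow(stand$traits))
  stand$rootfrac <- rootfrac_matrix(stand$traits, stand$soil)
  stand
}

#' Run the rooting-niche removal experiment
#'
#' Seed-paired comparison of drought responses with and without rooting
#' niche differentiation. Each pair shares founders and weather; both
#' branches run to the eve of the drought, then one branch has all rooting
#' traits homogenised to the deepest-rooting strategy's means
#' ([remove_root_niche()], applied on the first day of the drought year)
#' while the other is untouched; both then experience the identical drought.
#' A homogenised no-drought control is also run.
#'
#' @param pool Species pool for the founding communities.
#' @param n_pairs Number of seed-paired runs.
#' @param richness Founding richness per run (default 16).
#' @param site `"TNF"` or `"CAX"`.
#' @param cfg A [sim_config()] (evolution forced off).
#' @param seed Master seed.
#' @return A tibble with one row per pair: `bm_loss_intact`,
#'   `bm_loss_homog`, `bm_loss_homog_nodrought`, and
#'   `homog_lost_more` (logical).
#' @export
run_root_niche_experiment <- function(pool, n_pairs = 20, richness = 16,
                                      site = "TNF", cfg = sim_config(), seed) {
  cfg$evolution <- FALSE
  seeds <- matrix(seed_stream(seed, 3 * n_pairs), ncol = 3)
  rows <- purrr::map(seq_len(n_pairs), function(j) {
    fc_d <- experiment_forcing(site, cfg, drought = TRUE, seed = seeds[j, 1])
    fc_c <- experiment_forcing(site, cfg, drought = FALSE, seed = seeds[j, 1])
    ids <- with_seed(seeds[j, 2], sort(sample.int(nrow(pool), richness)))
    founders <- constrained_founders(pool, pool$species[ids], cfg$n_init)
    split_year <- fc_d$pre_census_year
    pre_weather <- fc_d$weather[fc_d$weather$year <= split_year, ]
    base <- run_stand(pre_weather, traits = founders, cfg = cfg,
                      seed = seeds[j, 3], census_years = split_year)
    agb_pre <- tail(base$annual$agb_t_ha, 1)
    if (agb_pre <= 0) {
      return(tibble::tibble(pair = j, bm_loss_intact = NA_real_,
                            bm_loss_homog = NA_real_,
                            bm_loss_homog_nodrought = NA_real_,
                            homog_lost_more = NA))
    }
    continue <- function(stand, weather_full) {
      ww <- weather_full[weather_full$year > split_year &
                           weather_full$year <= fc_d$end_year, ]
      run_stand(ww, cfg = cfg, seed = seeds[j, 3] + 1L, stand = stand)
    }
    stand_h <- remove_root_niche(base$final)
    run_i <- continue(base$final, fc_d$weather)
    run_h <- continue(stand_h, fc_d$weather)
    run_hc <- continue(stand_h, fc_c$weather)
    endv <- function(run) tail(run$annual$agb_t_ha, 1)
    li <- 100 * (agb_pre - endv(run_i)) / agb_pre
    lh <- 100 * (agb_pre - endv(run_h)) / agb_pre
    lhc <- 100 * (agb_pre - endv(run_hc)) / agb_pre
    tibble::tibble(pair = j, bm_loss_intact = li, bm_loss_homog = lh,
                   bm_loss_homog_nodrought = lhc,
                   homog_lost_more = lh >= li)
  })
  dplyr::bind_rows(rows)
}

#' Constrain the reachable strategy space of a configuration
#'
#' Level `"no_decid_water"` forbids the deciduous water-triggered strategy;
#' `"no_water_triggered"` additionally forbids the evergreen water-triggered
#' strategy (every plant becomes light-triggered). Initial populations,
#' recruitment and mutation all respect the constraint.
#'
#' @param cfg A [sim_config()].
#' @param level `"full"`, `"no_decid_water"` or `"no_water_triggered"`.
#' @return The modified config.
#' @export
strategy_removal_scenario <- function(cfg,
                                      level = c("full", "no_decid_water",
                                                "no_water_triggered")) {
  level <- match.arg(level)
  cfg$strategy_constraint <- level
  cfg
}
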