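# Multi-year simulation driver: daily physiology in compiled code, annual
# demography (mortality, reproduction with optional trait evolution,
# recruitment from the seed bank) in R.

# Advance the stand one year given that year's daily weather. Returns the
# updated stand plus the annual record and audit residuals.
annual_step <- function(stand, weather_year) {
  cfg <- stand$cfg
  light <- weather_year$light_index
  light_thresh <- min(light) + cfg$light_amp_frac * (max(light) - min(light))
  params <- list(
    es_max = cfg$es_max, psi_dry = cfg$psi_dry, psi_exp = cfg$psi_exp,
    e0 = cfg$e0, dd0 = cfg$dd0, amax = cfg$amax, kbeer = cfg$kbeer,
    rmaint = cfg$rmaint, rstem = cfg$rstem, root_turn = cfg$root_turn,
    stem_turn = cfg$stem_turn,
    plc_slope = cfg$plc_slope, closure_exp = cfg$closure_exp,
    uptake_wet_pref = cfg$uptake_wet_pref, uptake_rate = cfg$uptake_rate,
    layer_thickness_mm = stand$soil$thickness * 1000, plc_kill = cfg$plc_kill, d_kill = cfg$d_kill,
    plc_crit = cfg$plc_crit, store_crit = cfg$store_crit,
    flush_hi = cfg$flush_hi, flush_lo = cfg$flush_lo,
    flush_frac = cfg$flush_frac, flush_overhead = cfg$flush_overhead,
    refract_days = cfg$refract_days, dormancy_frac = cfg$dormancy_frac,
    h1 = cfg$h1, hexp = cfg$hexp, hhalf = cfg$hhalf, depth_cost = cfg$depth_cost,
    crown_area = cfg$crown_area,
    co2_half = cfg$co2_half, light_thresh = light_thresh,
    area_m2 = cfg$area_m2
  )
  res <- sim_year_cpp(stand$state, trait_matrix(stand$traits),
                      derived_matrix(stand$traits), stand$rootfrac,
                      stand$soil$water, stand$soil$cap, stand$soil$wilt,
                      weather_year$precip_mm, weather_year$tmean_C,
                      light, weather_year$co2_ppm[1], params)
  stand$state <- res$state
  stand$soil$water <- res$soil_water
  stand$year <- stand$year + 1L

  st <- stand$state
  deaths_hydraulic <- sum(st[, "alive"] < 0.5 & st[, "cause"] == 1)
  deaths_starv <- sum(st[, "alive"] < 0.5 & st[, "cause"] == 2)

  # annual mortality: storage exhausted at year end, background rate
  alive <- st[, "alive"] > 0.5
  starved <- alive & st[, "storage"] <= 1e-8
  st[starved, "alive"] <- 0
  st[starved, "cause"] <- 2
  deaths_starv <- deaths_starv + sum(starved)
  alive <- st[, "alive"] > 0.5
  bg <- alive & (runif(nrow(st)) < cfg$background_mortality)
  st[bg, "alive"] <- 0
  st[bg, "cause"] <- 3
  stand$state <- st

  stand <- reproduce_and_recruit(stand)

  rec <- dplyr::bind_cols(
    tibble::tibble(
      year = stand$year,
      agb_t_ha = stand_agb(stand),
      n_individuals = sum(stand$state[, "alive"] > 0.5),
      transpiration_mm = sum(res$transp_day)
    ),
    tibble::as_tibble_row(strategy_shares(stand)),
    tibble::tibble(
      deaths_hydraulic = deaths_hydraulic,
      deaths_starvation = deaths_starv,
      deaths_background = sum(bg)
    )
  )
  list(stand = stand, record = rec, transp_day = res$transp_day,
       water_resid_max = res$water_resid_max,
       carbon_resid_max = res$carbon_resid_max)
}

# Year-end reproduction (crossover + mutation when evolution is on), seed
# bank decay, recruitment draws, and compaction of dead individuals.
# The seed bank stores parent trait rows as plain named numeric vectors —
# this loop runs once per simulated year and must stay light.
reproduce_and_recruit <- function(stand) {
  cfg <- stand$cfg
  st <- stand$state
  alive <- st[, "alive"] > 0.5

  # reproduction: a_repro of storage moves to the reproduction pool
  repro_c <- stand$traits$a_repro * st[, "storage"] * alive
  st[, "storage"] <- st[, "storage"] - repro_c
  st[, "repro"] <- st[, "repro"] + repro_c
  n_seeds <- floor(st[, "repro"] / (stand$traits$seed_mass / 1000)) * alive
  st[, "repro"] <- st[, "repro"] - n_seeds * (stand$traits$seed_mass / 1000)
  stand$state <- st

  # seed bank: decay old cohorts, add this year's
  sb <- stand$seed_bank
  sb$count <- sb$count * cfg$seed_bank_survival
  sb <- sb[sb$count >= 0.5, , drop = FALSE]
  producers <- which(n_seeds > 0 & alive)
  trait_names <- trait_bounds()$trait
  if (length(producers) > 0) {
    pm <- as.matrix(stand$traits[producers, trait_names])
    new_cohorts <- tibble::tibble(
      species = stand$traits$species[producers],
      count = n_seeds[producers],
      traits = asplit(pm, 1)
    )
    sb <- dplyr::bind_rows(sb, new_cohorts)
  }
  stand$seed_bank <- sb

  # recruitment: sample cohorts by seed count; establishment saturates with
  # seed mass and declines with conspecific share (Janzen-Connell); traits
  # recombine within species when evolution is on
  space <- cfg$max_individuals - sum(stand$state[, "alive"] > 0.5)
  n_draws <- min(cfg$n_recruit_max, max(space, 0))
  recruits <- list()
  rspecies <- integer()
  if (n_draws > 0 && nrow(sb) > 0 && sum(sb$count) > 0) {
    draw_idx <- sample.int(nrow(sb), n_draws, replace = TRUE, prob = sb$count)
    alive_now <- stand$state[, "alive"] > 0.5
    n_alive <- sum(alive_now)
    sp_counts <- table(stand$traits$species[alive_now])
    consp_share <- function(sp) {
      if (n_alive == 0) return(0)
      cnt <- sp_counts[as.character(sp)]
      if (is.na(cnt)) 0 else unname(cnt) / n_alive
    }
    u_estab <- runif(length(draw_idx))
    for (k in seq_along(draw_idx)) {
      ci <- draw_idx[k]
      tr <- sb$traits[[ci]]
      estab_p <- tr[["seed_mass"]] / (tr[["seed_mass"]] + cfg$estab_half_sat)
      estab_p <- estab_p * (1 - cfg$jc_strength * consp_share(sb$species[ci]))
      if (u_estab[k] > estab_p) next
      if (cfg$evolution) {
        mates <- which(sb$species == sb$species[ci])
        if (length(mates) > 1) {
          mate <- if (length(mates) == 2) {
            setdiff(mates, ci)[1]
          } else {
            sample(mates, 1, prob = sb$count[mates])
          }
          tr <- crossover_traits(tr, sb$traits[[mate]], cfg$p_cross)
        }
        tr <- mutate_traits(tr, cfg$p_mut, cfg$mut_sd_frac, cfg$strategy_constraint)
      }
      recruits[[length(recruits) + 1]] <- tr
      rspecies <- c(rspecies, sb$species[ci])
    }
  }

  # compact: drop dead rows, append recruits (rooting profiles are kept for
  # survivors and computed only for the newcomers)
  keep <- stand$state[, "alive"] > 0.5
  traits <- stand$traits[keep, , drop = FALSE]
  state <- stand$state[keep, , drop = FALSE]
  rootfrac <- stand$rootfrac[keep, , drop = FALSE]
  if (length(recruits) > 0) {
    rtr <- tibble::as_tibble(do.call(rbind, recruits))
    rtr$species <- rspecies
    rst <- new_state(nrow(rtr), cfg)
    rst[, "storage"] <- rst[, "storage"] + rtr$seed_mass / 1000
    traits <- dplyr::bind_rows(traits, rtr)
    state <- rbind(state, rst)
    rootfrac <- rbind(rootfrac, rootfrac_matrix(rtr, stand$soil))
  }
  stand$traits <- traits
  stand$state <- state
  stand$rootfrac <- rootfrac
  stand
}

# Crossover and mutation on named numeric trait vectors.
crossover_traits <- function(tr1, tr2, p_cross) {
  take <- runif(length(tr1)) < p_cross
  tr1[take] <- tr2[take]
  renorm_alloc_vec(tr1)
}

mutate_traits <- function(tr, p_mut, mut_sd_frac, constraint = "full") {
  b <- trait_bounds()
  hit <- runif(nrow(b)) < p_mut
  for (i in which(hit)) {
    nm <- b$trait[i]
    if (b$kind[i] == "asymm") {
      tr[[nm]] <- 1 - tr[[nm]]
    } else {
      width <- b$upper[i] - b$lower[i]
      tr[[nm]] <- min(max(tr[[nm]] + rnorm(1, 0, mut_sd_frac * width),
                          b$lower[i]), b$upper[i])
    }
  }
  if (constraint == "no_decid_water" &&
      tr[["evergreen"]] == 0 && tr[["light_trigger"]] == 0) {
    tr[["light_trigger"]] <- 1
  } else if (constraint == "no_water_triggered" && tr[["light_trigger"]] == 0) {
    tr[["light_trigger"]] <- 1
  }
  renorm_alloc_vec(tr)
}

# Bounded-simplex renormalisation of the four allocation fractions for one
# named trait vector.
renorm_alloc_vec <- function(tr) {
  cols <- c("a_root", "a_stem", "a_leaf", "a_store")
  x <- pmin(pmax(tr[cols], 0.05), 0.6)
  fixed <- rep(FALSE, 4)
  for (pass in 1:6) {
    target <- 1 - sum(x[fixed])
    free <- which(!fixed)
    if (length(free) == 0 || target <= 0) break
    x[free] <- x[free] * target / sum(x[free])
    over <- free[x[free] > 0.6]
    under <- free[x[free] < 0.05]
    if (length(over) == 0 && length(under) == 0) break
    x[over] <- 0.6
    x[under] <- 0.05
    fixed[c(over, under)] <- TRUE
  }
  tr[cols] <- x
  tr
}

#' Run a stand simulation
#'
#' Drives a stand through every year covered by the daily weather series:
#' compiled daily physiology and water balance, then annual demography. All
#' randomness (background mortality, recruitment, evolution) derives from
#' `seed`; the same `(traits, weather, cfg, seed)` reproduces the run
#' bit-identically.
#'
#' @param weather Multi-year daily weather from [generate_daily_weather()]
#'   (optionally treated with [apply_drought()]).
#' @param traits Founding trait table (see [new_stand()]); `NULL` for
#'   uniform-random initialisation.
#' @param cfg A [sim_config()].
#' @param seed Integer seed (required).
#' @param census_years Years (1-based simulation years) at which to snapshot
#'   a full individual census.
#' @param stand An existing `stand` to continue from (its config is used);
#'   `traits` and `cfg` are then ignored.
#' @return A list of class `stand_run`: `annual` (one row per year),
#'   `daily_transpiration`, `censuses` (named list of census tibbles),
#'   `final` stand, and `audit` (max water/carbon residuals, mm and kg C).
#' @export
run_stand <- function(weather, traits = NULL, cfg = sim_config(), seed,
                      census_years = integer(), stand = NULL) {
  years <- unique(weather$year)
  if (any(diff(years) != 1)) stop("weather years must be consecutive", call. = FALSE)
  with_seed(seed, {
    stand <- stand %||% new_stand(traits, cfg)
    records <- vector("list", length(years))
    transp <- vector("list", length(years))
    censuses <- list()
    wres <- 0
    cres <- 0
    wsplit <- split(seq_len(nrow(weather)), weather$year)
    for (yi in seq_along(years)) {
      wy <- weather[wsplit[[as.character(years[yi])]], ]
      step <- annual_step(stand, wy)
      stand <- step$stand
      rec <- step$record
      rec$year <- years[yi]
      records[[yi]] <- rec
      transp[[yi]] <- tibble::tibble(year = years[yi], doy = 1:365,
                                     transpiration_mm = step$transp_day)
      wres <- max(wres, step$water_resid_max)
      cres <- max(cres, step$carbon_resid_max)
      if (years[yi] %in% census_years) {
        censuses[[as.character(years[yi])]] <- stand_census(stand)
      }
    }
    structure(
      list(
        annual = dplyr::bind_rows(records),
        daily_transpiration = dplyr::bind_rows(transp),
        censuses = censuses,
        final = stand,
        audit = c(water_resid_max_mm = wres, carbon_resid_max_kg = cres)
      ),
      class = "stand_run"
    )
  })
}

#' @export
print.stand_run <- function(x, ...) {
  ny <- nrow(x$annual)
  cat(sprintf("<stand_run> %d years; final AGB %.1f t/ha, %d individuals\n",
              ny, x$annual$agb_t_ha[ny], x$annual$n_individuals[ny]))
  invisible(x)
}

#' Individual census of a stand
#'
#' @param stand A `stand` object.
#' @return A tibble with one row per living individual: traits, strategy
#'   class, and carbon pools.
#' @export
stand_census <- function(stand) {
  alive <- stand$state[, "alive"] > 0.5
  tr <- stand$traits[alive, , drop = FALSE]
  st <- stand$state[alive, , drop = FALSE]
  dplyr::mutate(
    tibble::as_tibble(tr),
    strategy = classify_strategy(.data$evergreen, .data$light_trigger),
    leaf_kg = st[, "leaf"], stem_kg = st[, "stem"],
    root_kg = st[, "root"], storage_kg = st[, "storage"],
    agb_kg = st[, "stem"] + st[, "leaf"]
  )
}

#' Species abundances from a census
#'
#' Counts of living individuals per species, the abundance basis for the
#' diversity metrics.
#'
#' @param census A census tibble from [stand_census()].
#' @return A tibble `(species, n, abundance)` with `abundance` normalised.
#' @export
census_abundance <- function(census) {
  out <- dplyr::count(census, .data$species, name = "n")
  out$abundance <- out$n / sum(out$n)
  out
}
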