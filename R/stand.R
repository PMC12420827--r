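# Stand construction and configuration for the individual-based simulator.

#' Simulator configuration
#'
#' All tunable parameters of the stand simulator with desk-scale defaults.
#' Override any entry via `...`.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # site
    area_m2 = 1e4, latitude_deg = -3,
    # soil: 10 uniform layers over 10 m; per-metre field capacity and wilting
    soil_depth = 10, n_layers = 10, layer_thickness = NULL,
    cap_mm_per_m = 220, wilt_mm_per_m = 90,
    # physiology
    amax = 0.003,        # kg C m-2 leaf day-1 light-saturated gain
    e0 = 0.65,            # mm m-2 leaf day-1 transpiration demand scale
    es_max = 1.2,         # mm day-1 maximum soil evaporation
    kbeer = 0.35,         # Beer-Lambert canopy extinction
    rmaint = 3e-4,        # day-1 leaf+root maintenance respiration
    rstem = 1e-5,         # day-1 stem maintenance respiration
    depth_cost = 0.05,    # m-1 extra root maintenance per metre rooting depth
    root_turn = 1 / 1095, # day-1 fine-root turnover
    stem_turn = 1e-5,     # day-1 woody turnover (~0.4% yr-1)
    co2_half = 300,       # ppm Michaelis constant of the CO2 factor
    # hydraulics
    psi_dry = -10, psi_exp = 2, # soil water potential curve (MPa)
    dd0 = 0.4, closure_exp = 1, # stomatal closure exponent on (1 - plc)
    uptake_wet_pref = 1, # exponent of layer wetness in extraction weights
    uptake_rate = 2,      # mm day-1 per metre layer thickness at saturation            # MPa transpiration-induced water-potential drawdown scale
    plc_slope = 2,        # MPa-1 vulnerability-curve steepness
    # phenology
    flush_hi = 0.5, flush_lo = 0.3, # root-zone relative-water thresholds
    flush_frac = 0.5, flush_overhead = 0.2, refract_days = 21,
    dormancy_frac = 0.3, # leafless maintenance respiration multiplier
    light_amp_frac = 0.5, # light trigger: fraction of annual light amplitude
    # allometry
    h1 = 4, hexp = 0.35, hhalf = 30, crown_area = 2.5,
    # mortality
    plc_kill = 0.88, d_kill = 30, plc_crit = 0.5, store_crit = 0.01,
    background_mortality = 0.01,
    # reproduction and recruitment
    p_cross = 0.5, p_mut = 0.05, mut_sd_frac = 0.05,
    seed_bank_survival = 0.5,
    jc_strength = 0.8,    # conspecific density dependence at establishment
    n_recruit_max = 60, max_individuals = 360,
    estab_half_sat = 1.0, # g seed mass at half establishment probability
    # initial conditions
    n_init = 160,
    init_pools = c(leaf = 0.05, stem = 0.1, root = 0.05, storage = 0.4),
    # evolution switch and trait-space constraint
    evolution = TRUE,
    strategy_constraint = "full", # full | no_decid_water | no_water_triggered
    # scenario timing
    spinup_years = 150,
    co2_spinup = 286, co2_ambient = 380
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

# Soil column from a config. Layer thicknesses grade from a thin surface
# horizon (where rain arrives and evaporation competes with shallow roots)
# to thick deep storage layers; water is initialised at capacity.
new_soil <- function(cfg) {
  thick <- cfg$layer_thickness
  if (is.null(thick)) {
    thick <- c(0.25, 0.25, 0.5, 1, 1, 1, 2, 2, 1, 1)
  }
  thick <- thick * (cfg$soil_depth / sum(thick))
  list(
    thickness = thick,
    cap = thick * cfg$cap_mm_per_m,
    wilt = thick * cfg$wilt_mm_per_m,
    water = thick * cfg$cap_mm_per_m
  )
}

# Draw uniform random trait vectors within bounds (full-diversity
# initialisation), honouring any strategy constraint.
random_traits <- function(n, cfg) {
  b <- trait_bounds()
  cols <- lapply(seq_len(nrow(b)), function(i) {
    if (b$kind[i] == "asymm") {
      as.numeric(runif(n) < 0.5)
    } else {
      runif(n, b$lower[i], b$upper[i])
    }
  })
  names(cols) <- b$trait
  tr <- tibble::as_tibble(cols)
  tr <- normalize_allocation(tr)
  enforce_strategy_constraint(tr, cfg$strategy_constraint)
}

# Remap forbidden phenological combinations under a strategy-removal level.
enforce_strategy_constraint <- function(traits, level) {
  if (level == "full") return(traits)
  if (level == "no_decid_water") {
    bad <- traits$evergreen == 0 & traits$light_trigger == 0
    traits$light_trigger[bad] <- 1
  } else if (level == "no_water_triggered") {
    traits$light_trigger[traits$light_trigger == 0] <- 1
  } else {
    stop("unknown strategy constraint: ", level, call. = FALSE)
  }
  traits
}

STATE_COLS <- c("leaf", "stem", "root", "storage", "repro", "leaves_on",
                "plc", "consec", "alive", "stress_days", "cause", "refract")

new_state <- function(n, cfg) {
  st <- matrix(0, n, length(STATE_COLS), dimnames = list(NULL, STATE_COLS))
  st[, "leaf"] <- cfg$init_pools["leaf"]
  st[, "stem"] <- cfg$init_pools["stem"]
  st[, "root"] <- cfg$init_pools["root"]
  st[, "storage"] <- cfg$init_pools["storage"]
  st[, "leaves_on"] <- 1
  st[, "alive"] <- 1
  st
}

trait_matrix <- function(traits) {
  cbind(
    a_root = traits$a_root, a_stem = traits$a_stem, a_leaf = traits$a_leaf,
    a_store = traits$a_store, p50 = traits$p50,
    evergreen = traits$evergreen, light_trigger = traits$light_trigger,
    root_depth_max = traits$root_depth_max
  )
}

derived_matrix <- function(traits) {
  d <- derive_phenotype(traits$p50)
  cbind(sla = d$sla, longevity = d$leaf_longevity, kmax = d$k_stem_max)
}

rootfrac_matrix <- function(traits, soil) {
  t(vapply(seq_len(nrow(traits)), function(i) {
    root_fraction_profile(traits$root_depth_max[i], traits$root_shape[i],
                          soil$thickness)
  }, numeric(length(soil$thickness))))
}

#' Create a new simulation stand
#'
#' Builds the community state for one 1-ha stand: individuals with their
#' trait vectors and derived phenotypes, a layered soil column at field
#' capacity, and empty per-species seed banks.
#'
#' @param traits A trait tibble (one row per founding individual) with a
#'   `species` column, e.g. from [synth_species_pool()]; or `NULL` to draw
#'   `cfg$n_init` uniform-random trait vectors, each its own species.
#' @param cfg A [sim_config()].
#' @return A list of class `stand`.
#' @export
new_stand <- function(traits = NULL, cfg = sim_config()) {
  if (is.null(traits)) {
    traits <- random_traits(cfg$n_init, cfg)
    traits$species <- seq_len(nrow(traits))
  }
  if (!("species" %in% names(traits))) traits$species <- seq_len(nrow(traits))
  traits <- tibble::as_tibble(traits)
  soil <- new_soil(cfg)
  structure(
    list(
      traits = traits,
      state = new_state(nrow(traits), cfg),
      soil = soil,
      rootfrac = rootfrac_matrix(traits, soil),
      seed_bank = tibble::tibble(species = integer(), count = numeric(),
                                 traits = list()),
      year = 0L,
      cfg = cfg
    ),
    class = "stand"
  )
}

#' @export
print.stand <- function(x, ...) {
  alive <- sum(x$state[, "alive"] > 0.5)
  cat(sprintf("<stand> year %d: %d individuals alive (%d species), AGB %.1f t/ha\n",
              x$year, alive,
              length(unique(x$traits$species[x$state[, "alive"] > 0.5])),
              stand_agb(x)))
  invisible(x)
}

# Above-ground biomass (t/ha): stem + leaf carbon, doubled to dry biomass.
stand_agb <- function(stand) {
  alive <- stand$state[, "alive"] > 0.5
  sum((stand$state[alive, "stem"] + stand$state[alive, "leaf"])) * 2 / 1000
}

# Biomass share of the four phenological strategies among live individuals.
strategy_shares <- function(stand) {
  alive <- stand$state[, "alive"] > 0.5
  lv <- levels(classify_strategy(1, 1))
  out <- setNames(numeric(4), lv)
  if (!any(alive)) return(out)
  strat <- classify_strategy(stand$traits$evergreen[alive],
                             stand$traits$light_trigger[alive])
  bm <- stand$state[alive, "stem"] + stand$state[alive, "leaf"]
  tot <- sum(bm)
  if (tot <= 0) return(out)
  agg <- tapply(bm, strat, sum, default = 0)
  out[names(agg)] <- agg / tot
  out
}
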