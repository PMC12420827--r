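# Fast contract checks of the stand simulator; the long conservation audits
# and directional drought responses live in the acceptance suite.

small_cfg <- function(...) {
  sim_config(spinup_years = 10, n_init = 40, max_individuals = 80,
             n_recruit_max = 12, ...)
}

test_that("runs are bit-identical under a fixed seed", {
  cfg <- small_cfg()
  w <- flat_weather(6)
  r1 <- run_stand(w, cfg = cfg, seed = 33)
  r2 <- run_stand(w, cfg = cfg, seed = 33)
  expect_identical(r1$annual, r2$annual)
  expect_identical(r1$final$traits, r2$final$traits)
  r3 <- run_stand(w, cfg = cfg, seed = 34)
  expect_false(identical(r1$annual, r3$annual))
})

test_that("soil water only declines when there is no rain", {
  cfg <- small_cfg()
  wet <- flat_weather(2, precip_per_day = 6)
  run <- run_stand(wet, cfg = cfg, seed = 3)
  stand <- run$final
  dry <- flat_weather(1, precip_per_day = 0)
  soil_tot <- numeric(12)
  prev <- sum(stand$final_soil <- stand$soil$water)
  # step through the dry year month by month via the public driver
  dry_run <- run_stand(dry, cfg = cfg, seed = 4, stand = stand)
  expect_lt(sum(dry_run$final$soil$water), prev)
  expect_true(all(dry_run$final$soil$water >= stand$soil$wilt - 1e-9 |
                    dry_run$final$soil$water >= 0))
})

test_that("water and carbon budgets close over a multi-year run", {
  cfg <- small_cfg()
  fc <- experiment_forcing("TNF", cfg, drought = FALSE, seed = 6)
  run <- run_stand(fc$weather, cfg = cfg, seed = 7)
  expect_lt(run$audit["water_resid_max_mm"], 1e-6)
  expect_lt(run$audit["carbon_resid_max_kg"], 1e-9)
})

test_that("pools stay non-negative and traits stay in bounds under evolution", {
  cfg <- small_cfg(evolution = TRUE)
  fc <- experiment_forcing("TNF", cfg, drought = FALSE, seed = 16)
  run <- run_stand(fc$weather, cfg = cfg, seed = 17)
  st <- run$final$state
  expect_true(all(st[, c("leaf", "stem", "root", "storage", "repro")] >= 0))
  b <- trait_bounds()
  for (i in seq_len(nrow(b))) {
    v <- run$final$traits[[b$trait[i]]]
    expect_true(all(v >= b$lower[i] - 1e-9 & v <= b$upper[i] + 1e-9))
  }
  # allocation closure survives crossover and mutation
  a <- run$final$traits[c("a_root", "a_stem", "a_leaf", "a_store")]
  expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-9)
})

test_that("with evolution off every recruit matches a founder exactly", {
  pool <- demo_pool(6, seed = 20)
  cfg <- small_cfg(evolution = FALSE)
  founders <- hydrodiv:::constrained_founders(pool, pool$species, cfg$n_init)
  fc <- experiment_forcing("TNF", cfg, drought = FALSE, seed = 26)
  run <- run_stand(fc$weather, traits = founders, cfg = cfg, seed = 27)
  final_tr <- run$final$traits
  key <- function(df) apply(df[trait_bounds()$trait], 1, paste, collapse = "|")
  expect_true(all(key(final_tr) %in% key(pool)))
  # no new species labels appear
  expect_true(all(final_tr$species %in% pool$species))
})

test_that("strategy classification partitions every individual once", {
  cfg <- small_cfg()
  w <- flat_weather(4)
  run <- run_stand(w, cfg = cfg, seed = 55)
  shares <- run$annual[nrow(run$annual),
                       c("Evergreen_Light", "Evergreen_Water",
                         "Deciduous_Light", "Deciduous_Water")]
  if (run$annual$n_individuals[nrow(run$annual)] > 0) {
    expect_equal(sum(unlist(shares)), 1, tolerance = 1e-9)
  }
})

test_that("an emptied stand keeps recording and the run continues", {
  # certain death for every individual each year: the run must keep
  # emitting records with zero biomass instead of failing
  cfg <- small_cfg(background_mortality = 1)
  run <- run_stand(flat_weather(4), cfg = cfg, seed = 66)
  expect_equal(nrow(run$annual), 4)
  expect_true(all(run$annual$agb_t_ha >= 0))
  expect_equal(run$annual$n_individuals[4], 0)
  expect_equal(run$annual$agb_t_ha[4], 0)

  # soil keeps drying monotonically when rain stops entirely
  dry <- flat_weather(2, precip_per_day = 0)
  base <- run_stand(flat_weather(2), cfg = small_cfg(), seed = 3)
  dried <- run_stand(dry, cfg = small_cfg(), seed = 4, stand = base$final)
  expect_lt(sum(dried$final$soil$water), sum(base$final$soil$water))
})

test_that("seedling recruitment favours abundant seed producers", {
  # two species, one with tenfold seed output and equal seed mass: the
  # recruitment fraction approaches 10/11
  sb <- tibble::tibble(
    species = c(1L, 2L),
    count = c(1000, 100),
    traits = list(as.list(demo_pool(4, seed = 1)[1, ]),
                  as.list(demo_pool(4, seed = 1)[2, ]))
  )
  draws <- with(sb, {
    set.seed(8)
    table(sample(species, 20000, replace = TRUE, prob = count))
  })
  expect_equal(unname(draws["1"] / sum(draws)), 10 / 11, tolerance = 0.02)
})
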