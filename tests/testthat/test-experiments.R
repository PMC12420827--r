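test_that("the constrained-diversity design enumerates the full published grid", {
  man <- enumerate_diversity_design(seed = 9)
  expect_equal(nrow(man), 1728)
  expect_equal(length(unique(man$richness_level)), 18)
  expect_equal(max(table(man$richness_level)), 96)
  # species draws are without replacement and within the pool
  expect_true(all(vapply(man$species, function(s) !anyDuplicated(s), logical(1))))
  expect_true(all(unlist(man$species) %in% 1:96))
  # the drawn count matches the richness level
  expect_equal(lengths(man$species), man$richness_level)
  # seeds are unique and the manifest reproduces from the master seed
  expect_false(anyDuplicated(man$seed) > 0)
  man2 <- enumerate_diversity_design(seed = 9)
  expect_identical(man, man2)
  expect_error(enumerate_diversity_design(levels = c(4, 200), seed = 1),
               "exceeds")
})

test_that("founders replicate pool species to near-equal abundance", {
  pool <- demo_pool(8, seed = 13)
  f <- hydrodiv:::constrained_founders(pool, c(2, 5, 7), 40)
  expect_equal(nrow(f), 40)
  counts <- table(f$species)
  expect_setequal(names(counts), c("2", "5", "7"))
  expect_lte(max(counts) - min(counts), 1)
})

test_that("the evenness selector matches a brute-force scan", {
  mk <- function(id, s) {
    tibble::tibble(run_id = id, Evergreen_Light = s[1], Evergreen_Water = s[2],
                   Deciduous_Light = s[3], Deciduous_Water = s[4])
  }
  res <- dplyr::bind_rows(
    mk("a", c(0.4, 0.2, 0.2, 0.2)),
    mk("b", c(0.25, 0.25, 0.25, 0.25)),
    mk("c", c(0.7, 0.1, 0.1, 0.1)),   # below min share
    mk("d", c(0.5, 0.5, 0.0, 0.0))    # missing strategies
  )
  expect_equal(select_even_replicate(res), "b")
  # brute force: among eligible rows, maximise Pielou J
  shares <- as.matrix(res[levels(classify_strategy(1, 1))])
  elig <- apply(shares, 1, min) >= 0.2
  J <- apply(shares, 1, function(s) {
    s <- s[s > 0]; -sum(s * log(s)) / log(4)
  })
  expect_equal(select_even_replicate(res), res$run_id[elig][which.max(J[elig])])
  # a run with a missing strategy is never selected even if 'even'
  expect_error(select_even_replicate(res[3:4, ]), "enlarge")
})

test_that("root-niche removal homogenises only the rooting traits", {
  pool <- demo_pool(12, seed = 17)
  cfg <- sim_config(spinup_years = 4, n_init = 48, max_individuals = 60)
  founders <- hydrodiv:::constrained_founders(pool, pool$species, cfg$n_init)
  w <- flat_weather(4)
  run <- run_stand(w, traits = founders, cfg = cfg, seed = 5)
  stand <- run$final
  before <- stand$traits
  out <- remove_root_niche(stand)
  expect_equal(var(out$traits$root_depth_max), 0)
  expect_equal(var(out$traits$root_shape), 0)
  # the overwrite uses the deepest strategy's means
  strat <- classify_strategy(before$evergreen, before$light_trigger)
  alive <- stand$state[, "alive"] > 0.5
  mdepth <- tapply(before$root_depth_max[alive], strat[alive], mean)
  expect_equal(out$traits$root_depth_max[1], max(mdepth, na.rm = TRUE),
               tolerance = 1e-12)
  # every other trait is bit-identical
  others <- setdiff(names(before), c("root_depth_max", "root_shape"))
  expect_identical(before[others], out$traits[others])
  # empty stand errors
  stand$state[, "alive"] <- 0
  expect_error(remove_root_niche(stand), "empty")
})

test_that("strategy removal constrains the reachable trait space", {
  cfg2 <- strategy_removal_scenario(sim_config(), "no_decid_water")
  expect_equal(cfg2$strategy_constraint, "no_decid_water")
  tr <- hydrodiv:::random_traits(500, cfg2)
  st <- classify_strategy(tr$evergreen, tr$light_trigger)
  expect_equal(sum(st == "Deciduous_Water"), 0)
  expect_gt(sum(st == "Evergreen_Water"), 0)

  cfg3 <- strategy_removal_scenario(sim_config(), "no_water_triggered")
  tr3 <- hydrodiv:::random_traits(500, cfg3)
  st3 <- classify_strategy(tr3$evergreen, tr3$light_trigger)
  expect_equal(sum(st3 %in% c("Deciduous_Water", "Evergreen_Water")), 0)

  # full keeps all four reachable
  trf <- hydrodiv:::random_traits(500, sim_config())
  expect_equal(length(unique(classify_strategy(trf$evergreen, trf$light_trigger))), 4)

  # a constrained short run never hosts a forbidden strategy
  cfg_run <- sim_config(spinup_years = 6, n_init = 40, max_individuals = 60,
                        strategy_constraint = "no_decid_water")
  run <- run_stand(flat_weather(6), cfg = cfg_run, seed = 77)
  cs <- stand_census(run$final)
  if (nrow(cs) > 0) expect_equal(sum(cs$strategy == "Deciduous_Water"), 0)
})

test_that("pool building takes the most abundant species' mean traits", {
  pool <- demo_pool(4, seed = 23)
  # fabricate censuses: replicate 1 monoculture of species 3; replicate 2
  # dominated by species 1 (by count)
  mono <- dplyr::mutate(pool[rep(3, 5), ],
                        strategy = classify_strategy(evergreen, light_trigger),
                        agb_kg = 10)
  mixed <- dplyr::mutate(pool[c(1, 1, 1, 2, 2), ],
                         strategy = classify_strategy(evergreen, light_trigger),
                         agb_kg = c(1, 1, 1, 50, 50))
  res <- tibble::tibble(census = list(mono, mixed))
  built <- build_species_pool(res, pool_size = 2)
  expect_equal(nrow(built), 2)
  expect_equal(built$p50[1], pool$p50[3])        # monoculture entry is exact
  expect_equal(built$p50[2], pool$p50[1])        # count beats biomass
  b <- trait_bounds()
  for (i in seq_len(nrow(b))) {
    expect_true(all(built[[b$trait[i]]] >= b$lower[i] - 1e-9 &
                      built[[b$trait[i]]] <= b$upper[i] + 1e-9))
  }
  # zero-survivor replicates are skipped with a warning
  res2 <- tibble::tibble(census = list(mono, mono[0, ], mixed))
  expect_warning(built2 <- build_species_pool(res2, pool_size = 2),
                 "skipped")
  expect_equal(nrow(built2), 2)
  expect_error(suppressWarnings(build_species_pool(res2, pool_size = 3)),
               "contributing")
})
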