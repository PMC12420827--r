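true_coefs <- list(
  intercept = -20, precip_1990 = 5, raoq = 8, precip_change = -15,
  rcp85 = -6, co2_fixed = -10, raoq_x_precip_change = 4
)

test_that("the mixed model recovers planted continental coefficients", {
  g <- synth_continental_grid(n_sites = 150, coefs = true_coefs,
                              site_sd = 5, sigma = 6, seed = 41)
  fit <- fit_lmm(g)
  td <- tidy(fit)
  pick <- function(term) td[td$term == term, ]
  mapping <- c(precip_1990 = "precip_1990", raoq = "raoq",
               precip_change = "precip_change", rcp85 = "rcprcp85",
               co2_fixed = "co2fixed",
               raoq_x_precip_change = "raoq:precip_change")
  # six simultaneous intervals: use a Bonferroni-widened z so the joint
  # coverage matches the nominal level
  z6 <- qnorm(1 - 0.05 / (2 * 6))
  for (nm in names(mapping)) {
    row <- pick(mapping[[nm]])
    expect_equal(nrow(row), 1)
    expect_lt(row$estimate - z6 * row$std.error, true_coefs[[nm]])
    expect_gt(row$estimate + z6 * row$std.error, true_coefs[[nm]])
  }
  # the single preplanned contrast (diversity x drought) at the plain 95% level
  ia <- pick("raoq:precip_change")
  expect_lt(ia$conf.low, true_coefs$raoq_x_precip_change)
  expect_gt(ia$conf.high, true_coefs$raoq_x_precip_change)
  # the diversity x drought interaction survives AIC pruning
  expect_true("raoq:precip_change" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(g))
  expect_gt(gl$r2_conditional, gl$r2_marginal)
})

test_that("without site variance marginal and conditional R2 coincide", {
  g <- synth_continental_grid(n_sites = 120, coefs = true_coefs,
                              site_sd = 0, sigma = 6, seed = 43)
  fit <- suppressWarnings(fit_lmm(g, prune = FALSE))
  expect_equal(unname(fit$r2["marginal"]), unname(fit$r2["conditional"]),
               tolerance = 0.02)
})

test_that("prediction grids evaluate the fitted fixed-effect surface", {
  g <- synth_continental_grid(n_sites = 120, coefs = true_coefs, seed = 45)
  fit <- fit_lmm(g, prune = FALSE)
  pe <- predict_diversity_effect(fit, baseline = 2500,
                                 reductions = c(750, 1000, 1250))
  expect_setequal(unique(pe$curves$precip_change), c(750, 1000, 1250))
  expect_equal(pe$effects$reduction_pct, c(30, 40, 50))

  # algebraic oracle: reproduce one prediction directly from fixef + scaling
  fx <- lme4::fixef(fit$model)
  row <- pe$curves[17, ]
  z <- function(v, nm) (v - fit$centers[nm]) / fit$scales[nm]
  manual <- unname(
    fx["(Intercept)"] +
      fx["precip_1990"] * z(row$precip_1990, "precip_1990") +
      fx["raoq"] * z(row$raoq, "raoq") +
      fx["precip_change"] * z(row$precip_change, "precip_change") +
      fx["precip_1990:raoq"] * z(row$precip_1990, "precip_1990") * z(row$raoq, "raoq") +
      fx["precip_1990:precip_change"] * z(row$precip_1990, "precip_1990") *
        z(row$precip_change, "precip_change") +
      fx["raoq:precip_change"] * z(row$raoq, "raoq") * z(row$precip_change, "precip_change")
  )
  expect_equal(row$pred, manual, tolerance = 1e-9)

  # a positive planted diversity x drought interaction means the diversity
  # effect grows with the reduction level
  eff <- pe$effects$diversity_effect
  expect_true(all(diff(eff) > 0))
  expect_gt(eff[3], 0)
})

test_that("a zero interaction yields equal diversity effects at all levels", {
  coefs0 <- true_coefs
  coefs0$raoq_x_precip_change <- 0
  g <- synth_continental_grid(n_sites = 150, coefs = coefs0, sigma = 3,
                              site_sd = 2, seed = 47)
  fit <- fit_lmm(g, prune = FALSE)
  pe <- predict_diversity_effect(fit)
  eff <- pe$effects$diversity_effect
  expect_lt(max(eff) - min(eff), 2.5) # equal up to sampling noise
})

test_that("site filtering applies inclusive boundaries", {
  tb <- tibble::tibble(
    agb_1990 = c(175, 149, 175, 150, 200, 201),
    precip_change = c(300, 300, 249, 250, 250, 300)
  )
  out <- filter_sites(tb)
  expect_equal(nrow(out), 3)
  expect_true(all(out$agb_1990 >= 150 & out$agb_1990 <= 200))
  expect_equal(nrow(filter_sites(tb[0, ])), 0)
  expect_error(filter_sites(tb["agb_1990"]), "missing")
})

test_that("AIC pruning removes interactions absent from the data", {
  # response built with NO interactions at all: pruning should drop most
  coefs0 <- list(intercept = -20, precip_1990 = 5, raoq = 8,
                 precip_change = -15, rcp85 = -6, co2_fixed = -10,
                 raoq_x_precip_change = 0)
  g <- synth_continental_grid(n_sites = 100, coefs = coefs0, sigma = 4,
                              site_sd = 2, seed = 49)
  fit <- fit_lmm(g, prune = TRUE)
  expect_lt(length(fit$interactions), 10) # started from 10 two-way terms
  expect_gte(nrow(fit$aic_path), 1)
  expect_true(all(diff(fit$aic_path$aic) < 0))
})
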