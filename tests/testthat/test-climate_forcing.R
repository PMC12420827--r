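ser_tbl <- function(values, start_year = 1850) {
  ny <- ceiling(length(values) / 12)
  g <- tidyr::expand_grid(year = start_year + seq_len(ny) - 1, month = 1:12)
  g <- g[seq_along(values), ]
  g$value <- values
  g
}

test_that("quadratic anomaly trend recovers planted coefficients", {
  # constant series
  fit <- fit_anomaly_trend(ser_tbl(rep(5, 48)), "temperature")
  expect_equal(fit$intercept, 5, tolerance = 1e-12)
  expect_equal(fit$coef, 0, tolerance = 1e-12)
  expect_equal(fit$sse, 0, tolerance = 1e-12)

  # noiseless quadratic in the month index
  m <- 0:3011
  fit2 <- fit_anomaly_trend(ser_tbl(2 + 0.001 * m^2), "precipitation")
  expect_equal(fit2$intercept, 2, tolerance = 1e-8)
  expect_equal(fit2$coef, 0.001, tolerance = 1e-8)
})

test_that("least-squares SSE matches a brute-force grid search", {
  m <- 0:499
  set.seed(1)
  y <- 2 + 0.001 * m^2 + rnorm(500, 0, 0.3)
  fit <- fit_anomaly_trend(ser_tbl(y), "temperature")
  grid_a <- seq(fit$intercept - 0.2, fit$intercept + 0.2, length.out = 81)
  grid_b <- seq(fit$coef * 0.9, fit$coef * 1.1, length.out = 81)
  sse_grid <- min(outer(grid_a, grid_b, Vectorize(function(a, b) {
    sum((y - a - b * m^2)^2)
  })))
  expect_equal(fit$sse, sse_grid, tolerance = 1e-3 * sse_grid)
  expect_lte(fit$sse, sse_grid + 1e-9)
})

test_that("anomaly fitting rejects bad input", {
  expect_error(fit_anomaly_trend(ser_tbl(rep(1, 12))), "at least 24")
  expect_error(fit_anomaly_trend(ser_tbl(c(rep(1, 30), NA, rep(1, 5)))),
               "missing or non-finite")
})

test_that("normalisation pins the reference-window mean to 0 / 1", {
  g <- tidyr::expand_grid(year = 1990:2020, month = 1:12)
  g$value <- 20 + 0.01 * seq_len(nrow(g)) # linear trend

  tn <- normalize_anomalies(g, variable = "temperature")
  expect_equal(mean(tn$value[tn$year %in% 2001:2010]), 0, tolerance = 1e-9)

  pn <- normalize_anomalies(g, variable = "precipitation")
  expect_equal(mean(pn$value[pn$year %in% 2001:2010]), 1, tolerance = 1e-9)
  expect_true(all(pn$value >= 0))

  # constants map to exactly 0 / 1
  gc <- g; gc$value <- 3.2
  expect_true(all(normalize_anomalies(gc, variable = "temperature")$value == 0))
  gc$value <- 0.8
  expect_true(all(normalize_anomalies(gc, variable = "precipitation")$value == 1))

  gneg <- g; gneg$value <- -1
  expect_error(normalize_anomalies(gneg, variable = "precipitation"), "positive")
})

test_that("climatology scaling is additive in T and multiplicative in P", {
  clim <- synth_climatology(site_spec("TNF"), seed = 1)
  yrs <- 2000:2004
  tanom <- tidyr::expand_grid(year = yrs, month = 1:12)
  tanom$value <- runif(nrow(tanom), -1, 1)
  panom <- tidyr::expand_grid(year = yrs, month = 1:12)
  panom$value <- runif(nrow(panom), 0.5, 1.5)

  out <- scale_climatology(clim, tanom, panom)
  # element-wise oracle
  for (k in sample.int(nrow(out), 20)) {
    row <- out[k, ]
    t0 <- clim$tmean_C[clim$month == row$month]
    p0 <- clim$precip_mm[clim$month == row$month]
    ta <- tanom$value[tanom$year == row$year & tanom$month == row$month]
    pa <- panom$value[panom$year == row$year & panom$month == row$month]
    expect_equal(row$tmean_C, t0 + ta)
    expect_equal(row$precip_mm, p0 * pa)
  }
  # identity anomalies reproduce the climatology
  tanom$value <- 0
  panom$value <- 1
  id <- scale_climatology(clim, tanom, panom)
  expect_equal(id$precip_mm, rep(clim$precip_mm, length(yrs)))
  expect_equal(id$tmean_C, rep(clim$tmean_C, length(yrs)))
})

test_that("daily weather generator honours its contract", {
  clim <- synth_climatology(site_spec("TNF"), seed = 1)

  # dry limit
  dry <- clim
  dry$precip_mm <- 0
  w0 <- generate_daily_weather(dry, seed = 4, years = 1:2)
  expect_true(all(w0$precip_mm == 0))
  expect_equal(nrow(w0), 730)

  # determinism and structure
  w1 <- generate_daily_weather(clim, seed = 11, years = 1:3)
  w2 <- generate_daily_weather(clim, seed = 11, years = 1:3)
  expect_identical(w1, w2)
  w3 <- generate_daily_weather(clim, seed = 12, years = 1:3)
  expect_false(identical(w1$precip_mm, w3$precip_mm))
  expect_true(all(w1$precip_mm >= 0))
  expect_true(all(w1$light_index >= 0 & w1$light_index <= 1))
  expect_equal(unique(table(w1$year)), 365L)

  # missing seed errors
  expect_error(generate_daily_weather(clim, years = 1), "seed")
})

test_that("monthly totals and wet-day counts match expectation", {
  # moderate Monte-Carlo version of the calibration (full run in acceptance)
  clim <- tibble::tibble(month = 1:12, precip_mm = 150, rain_days = 10,
                         tmean_C = 26, trange_C = 9, sun_frac = 0.5)
  nyr <- 200 # 2400 months
  w <- generate_daily_weather(clim, seed = 5, years = seq_len(nyr))
  totals <- tapply(w$precip_mm, list(w$year, w$month), sum)
  wet <- tapply(w$precip_mm > 0, list(w$year, w$month), sum)
  expect_equal(mean(totals), 150, tolerance = 0.03)
  expect_equal(mean(wet), 10, tolerance = 1e-12)
})

test_that("drought treatment halves treated years and leaves the rest alone", {
  clim <- synth_climatology(site_spec("CAX"), seed = 2)
  w <- generate_daily_weather(clim, seed = 3, years = 1:10)
  wd <- apply_drought(w, start_year = 4, duration_years = 7, fraction = 0.5)
  tot <- tapply(w$precip_mm, w$year, sum)
  totd <- tapply(wd$precip_mm, wd$year, sum)
  expect_equal(unname(totd[4:10]), unname(tot[4:10]) / 2)
  expect_equal(unname(totd[1:3]), unname(tot[1:3]))
  expect_identical(wd$tmean_C, w$tmean_C) # non-precip fields untouched

  expect_identical(apply_drought(w, 4, 2, 0), w) # identity at fraction 0
  expect_error(apply_drought(w, 4, 2, 1.2), "fraction")
  expect_error(apply_drought(w, 9, 5, 0.5), "beyond")
})

test_that("reduction percentages follow the baseline arithmetic", {
  expect_equal(reduction_percent(2500, 750), 30)
  expect_equal(reduction_percent(2500, 1250), 50)
  expect_equal(reduction_percent(2500, 1000), 40)
  expect_equal(reduction_percent(1234, 0), 0)
  expect_error(reduction_percent(0, 0), "positive")
  expect_error(reduction_percent(100, 150), "baseline")
})
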