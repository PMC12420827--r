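#' Fit a quadratic anomaly trend to a monthly climate series
#'
#' Long-run monthly series of temperature or precipitation are summarised by a
#' two-parameter quadratic trend that is later normalised over a reference
#' decade and used to scale a monthly climatology. The default regresses the
#' monthly value on the squared month index since the series start
#' (`value ~ intercept + coef * m^2`), i.e. a smooth accelerating trend in
#' time. `form = "value"` instead regresses the fitted value on the squared
#' observation itself; it is retained as an alternative reading of the
#' trend definition but is not used by the rest of the pipeline.
#'
#' @param data A data frame with columns `year`, `month` and `value`
#'   (temperature in deg C or monthly precipitation in mm), in time order.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param form Covariate of the quadratic: `"month"` (default, squared month
#'   index) or `"value"` (squared observation).
#' @return An object of class `anomaly_fit`: a list with `intercept`, `coef`,
#'   `sse`, `variable`, `form` and `fitted`, a tibble of `(year, month,
#'   value)` fitted values.
#' @examples
#' ser <- tidyr::expand_grid(year = 1850:1899, month = 1:12)
#' ser$value <- 25 + 1e-6 * (seq_len(nrow(ser)) - 1)^2
#' fit <- fit_anomaly_trend(ser, "temperature")
#' c(fit$intercept, fit$coef)
#' @export
fit_anomaly_trend <- function(data,
                              variable = c("temperature", "precipitation"),
                              form = c("month", "value")) {
  variable <- match.arg(variable)
  form <- match.arg(form)
  assert_cols(data, c("year", "month", "value"), "anomaly series")
  y <- data$value
  if (length(y) < 24) stop("need at least 24 monthly values", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y))) {
    stop("anomaly series contains missing or non-finite values", call. = FALSE)
  }
  x2 <- switch(form,
    month = (seq_along(y) - 1)^2,
    value = y^2
  )
  fit <- stats::lm.fit(cbind(1, x2), y)
  cf <- unname(fit$coefficients)
  if (anyNA(cf)) cf[is.na(cf)] <- 0 # degenerate covariate (e.g. constant y under form = "value")
  fitted <- cf[1] + cf[2] * x2
  structure(
    list(
      intercept = cf[1], coef = cf[2],
      sse = sum((y - fitted)^2),
      variable = variable, form = form,
      fitted = tibble::tibble(year = data$year, month = data$month,
                              value = fitted)
    ),
    class = "anomaly_fit"
  )
}

#' @export
print.anomaly_fit <- function(x, ...) {
  cat(sprintf("<anomaly_fit> %s (%s form): intercept = %.6g, coef = %.6g, SSE = %.6g\n",
              x$variable, x$form, x$intercept, x$coef, x$sse))
  invisible(x)
}

#' Normalise fitted anomalies over a reference window
#'
#' Temperature anomalies are additive offsets centred so their mean over the
#' reference window is zero; precipitation anomalies are multiplicative
#' factors scaled so their mean over the reference window is one. Negative
#' precipitation factors are clipped at zero with a warning.
#'
#' @param fitted An `anomaly_fit` object or a data frame with `year`, `month`,
#'   `value` columns of fitted values.
#' @param reference_window Two years (inclusive) defining the reference
#'   period; default `c(2001, 2010)`.
#' @param variable `"temperature"` or `"precipitation"`; taken from the fit
#'   when `fitted` is an `anomaly_fit`.
#' @return A tibble `(year, month, value)`; class the anomaly series.
#' @export
normalize_anomalies <- function(fitted, reference_window = c(2001, 2010),
                                variable = NULL) {
  if (inherits(fitted, "anomaly_fit")) {
    variable <- variable %||% fitted$variable
    fitted <- fitted$fitted
  }
  if (is.null(variable)) {
    stop("`variable` must be supplied when `fitted` is a plain table",
         call. = FALSE)
  }
  variable <- match.arg(variable, c("temperature", "precipitation"))
  assert_cols(fitted, c("year", "month", "value"), "fitted anomalies")
  in_window <- fitted$year >= reference_window[1] &
    fitted$year <= reference_window[2]
  if (!any(in_window)) {
    stop("fitted series does not cover the reference window", call. = FALSE)
  }
  ref_mean <- mean(fitted$value[in_window])
  out <- tibble::as_tibble(fitted[c("year", "month", "value")])
  if (variable == "temperature") {
    out$value <- out$value - ref_mean
  } else {
    if (ref_mean <= 0) {
      stop("precipitation reference-window mean must be positive", call. = FALSE)
    }
    out$value <- out$value / ref_mean
    if (any(out$value < 0)) {
      warning("negative precipitation anomalies clipped at zero")
      out$value <- pmax(out$value, 0)
    }
  }
  out
}

#' Scale a monthly climatology by anomaly series
#'
#' Temperature anomalies are added to the climatological monthly means;
#' precipitation anomalies multiply the climatological monthly totals. All
#' other climatology fields are passed through unchanged.
#'
#' @param clim A 12-row monthly climatology with columns `month`, `precip_mm`,
#'   `rain_days`, `tmean_C` (and optionally `trange_C`, `sun_frac`).
#' @param tanom,panom Anomaly series tibbles `(year, month, value)` as
#'   returned by [normalize_anomalies()]. Either may be `NULL` for an
#'   identity treatment.
#' @param years Optional vector of years to assemble; defaults to the years
#'   common to both anomaly series.
#' @return A tibble with one row per (year, month) of monthly forcing.
#' @export
scale_climatology <- function(clim, tanom = NULL, panom = NULL, years = NULL) {
  clim <- validate_climatology(clim)
  if (is.null(years)) {
    yrs <- lapply(list(tanom, panom), function(a) if (is.null(a)) NULL else unique(a$year))
    yrs <- yrs[!vapply(yrs, is.null, logical(1))]
    if (length(yrs) == 0) stop("supply `years` or at least one anomaly series", call. = FALSE)
    years <- sort(Reduce(intersect, yrs))
  }
  out <- tidyr::expand_grid(year = years, clim)
  lookup <- function(anom, default) {
    if (is.null(anom)) return(rep(default, nrow(out)))
    key <- paste(out$year, out$month)
    v <- anom$value[match(key, paste(anom$year, anom$month))]
    if (anyNA(v)) stop("anomaly series does not cover all requested (year, month)", call. = FALSE)
    v
  }
  out$tmean_C <- out$tmean_C + lookup(tanom, 0)
  out$precip_mm <- out$precip_mm * lookup(panom, 1)
  out
}

validate_climatology <- function(clim) {
  assert_cols(clim, c("month", "precip_mm", "rain_days", "tmean_C"),
              "monthly climatology")
  if (nrow(clim) != 12 || !setequal(clim$month, 1:12)) {
    stop("climatology must have exactly 12 rows, months 1..12", call. = FALSE)
  }
  if (any(clim$precip_mm < 0)) stop("precip_mm must be >= 0", call. = FALSE)
  if (any(clim$rain_days < 0 | clim$rain_days > 31)) {
    stop("rain_days must lie in [0, 31]", call. = FALSE)
  }
  tibble::as_tibble(clim[order(clim$month), ])
}

#' Generate daily weather from monthly forcing
#'
#' A stochastic weather generator: for each month, `round(rain_days)` wet days
#' (at least one whenever the monthly total is positive) are placed uniformly
#' at random without replacement among that month's days, and each event
#' amount is drawn from a gamma distribution with shape `gamma_shape` and
#' mean `precip_mm / n_wet_days`, so the expected monthly total equals the
#' monthly forcing. Daily temperature interpolates linearly between monthly
#' means anchored at month midpoints; `light_index` is a normalised
#' top-of-atmosphere insolation proxy for the site latitude. Years have 365
#' days.
#'
#' @param monthly A monthly forcing table with columns `year`, `month`,
#'   `precip_mm`, `tmean_C` (e.g. from [scale_climatology()], or a 12-row
#'   climatology, in which case `years` must be given).
#' @param seed Integer seed (required; the generator is stochastic).
#' @param latitude_deg Site latitude in degrees (default -3, eastern
#'   Amazonia).
#' @param co2_ppm CO2 pathway: a single value held constant, or a data frame
#'   `(year, co2_ppm)`.
#' @param gamma_shape Shape parameter k of the event-size gamma distribution
#'   (default 1, i.e. exponential event sizes).
#' @param years Optional years to expand a bare 12-row climatology over.
#' @return A tibble of daily weather: `year`, `doy`, `month`, `precip_mm`,
#'   `tmean_C`, `light_index`, `co2_ppm`.
#' @export
generate_daily_weather <- function(monthly, seed, latitude_deg = -3,
                                   co2_ppm = 380, gamma_shape = 1,
                                   years = NULL) {
  if (!("year" %in% names(monthly))) {
    if (is.null(years)) stop("supply `years` when passing a bare climatology", call. = FALSE)
    monthly <- tidyr::expand_grid(year = years, validate_climatology(monthly))
  }
  assert_cols(monthly, c("year", "month", "precip_mm", "tmean_C"), "monthly forcing")
  if (!("rain_days" %in% names(monthly))) monthly$rain_days <- 10
  monthly <- dplyr::arrange(monthly, .data$year, .data$month)
  yrs <- unique(monthly$year)
  light <- light_index_series(latitude_deg)

  co2_of_year <- if (is.data.frame(co2_ppm)) {
    assert_cols(co2_ppm, c("year", "co2_ppm"), "CO2 pathway")
    function(y) {
      v <- co2_ppm$co2_ppm[match(y, co2_ppm$year)]
      if (anyNA(v)) stop("CO2 pathway does not cover all simulation years", call. = FALSE)
      v
    }
  } else {
    function(y) rep(as.numeric(co2_ppm), length(y))
  }

  with_seed(seed, {
    n_days_total <- 365L * length(yrs)
    precip <- numeric(n_days_total)
    offset <- 0L
    for (yi in seq_along(yrs)) {
      my <- monthly[monthly$year == yrs[yi], ]
      if (nrow(my) != 12) stop("each year needs 12 monthly rows", call. = FALSE)
      day0 <- c(0L, cumsum(DAYS_PER_MONTH))
      for (m in 1:12) {
        r_m <- my$precip_mm[my$month == m]
        w_m <- my$rain_days[my$month == m]
        if (r_m <= 0) next
        n_wet <- max(1L, as.integer(round(w_m)))
        n_wet <- min(n_wet, DAYS_PER_MONTH[m])
        wet_days <- sample.int(DAYS_PER_MONTH[m], n_wet)
        amounts <- rgamma(n_wet, shape = gamma_shape,
                          scale = r_m / (n_wet * gamma_shape))
        precip[offset + day0[m] + wet_days] <- amounts
      }
      offset <- offset + 365L
    }
    tmean <- unlist(lapply(yrs, function(y) {
      interp_monthly_to_daily(monthly$tmean_C[monthly$year == y][order(monthly$month[monthly$year == y])])
    }), use.names = FALSE)
    tibble::tibble(
      year = rep(yrs, each = 365L),
      doy = rep(1:365, times = length(yrs)),
      month = rep(MONTH_OF_DOY, times = length(yrs)),
      precip_mm = precip,
      tmean_C = tmean,
      light_index = rep(light, times = length(yrs)),
      co2_ppm = rep(co2_of_year(yrs), each = 365L)
    )
  })
}

# Linear interpolation of 12 monthly values to 365 daily values, anchored at
# month midpoints and wrapping around the year.
interp_monthly_to_daily <- function(mv) {
  stopifnot(length(mv) == 12)
  mid <- cumsum(DAYS_PER_MONTH) - DAYS_PER_MONTH / 2
  x <- c(mid[12] - 365, mid, mid[1] + 365)
  y <- c(mv[12], mv, mv[1])
  stats::approx(x, y, xout = 1:365)$y
}

# Normalised daily top-of-atmosphere insolation proxy (noon solar elevation,
# clamped at 0 and scaled to a [0, 1] annual maximum of 1).
light_index_series <- function(latitude_deg) {
  doy <- 1:365
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  lat <- latitude_deg * pi / 180
  elev <- sin(lat) * sin(decl) + cos(lat) * cos(decl)
  elev <- pmax(elev, 0)
  elev / max(elev)
}

#' Apply a through-fall-exclusion drought treatment
#'
#' Multiplies daily precipitation by `1 - fraction` for every day of the
#' treatment window; all other days and all non-precipitation fields are
#' untouched.
#'
#' @param weather Daily weather tibble from [generate_daily_weather()].
#' @param start_year First treated year.
#' @param duration_years Number of consecutive treated years.
#' @param fraction Fraction of precipitation removed, in `[0, 1]` (0.5 for
#'   the TNF- and CAX-style protocols).
#' @return The treated daily weather tibble.
#' @export
apply_drought <- function(weather, start_year, duration_years, fraction) {
  assert_cols(weather, c("year", "precip_mm"), "daily weather")
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  yrs <- start_year:(start_year + duration_years - 1)
  if (!all(yrs %in% weather$year)) {
    stop("treatment window extends beyond the weather series", call. = FALSE)
  }
  sel <- weather$year %in% yrs
  weather$precip_mm[sel] <- (1 - fraction) * weather$precip_mm[sel]
  weather
}

#' Express a precipitation reduction as a percentage of baseline
#'
#' @param baseline_mm Baseline annual precipitation (mm), positive.
#' @param reduction_mm Reduction (mm), between 0 and the baseline.
#' @return `100 * reduction_mm / baseline_mm`.
#' @examples
#' reduction_percent(2500, 750)  # 30
#' reduction_percent(2500, 1250) # 50
#' @export
reduction_percent <- function(baseline_mm, reduction_mm) {
  if (any(baseline_mm <= 0)) stop("baseline must be positive", call. = FALSE)
  if (any(reduction_mm < 0 | reduction_mm > baseline_mm)) {
    stop("reduction must lie in [0, baseline]", call. = FALSE)
  }
  100 * reduction_mm / baseline_mm
}
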