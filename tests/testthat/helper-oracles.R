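# Independent brute-force oracles used across tests. These deliberately share
# no code with the package implementations.

# Double-loop Gower dissimilarity with asymmetric-binary exclusion.
oracle_gower <- function(tr, kinds, ranges) {
  n <- nrow(tr)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0
      cnt <- 0
      for (nm in names(tr)) {
        xi <- tr[[nm]][i]
        xj <- tr[[nm]][j]
        if (kinds[nm] == "asymm") {
          if (xi == 0 && xj == 0) next
          num <- num + as.numeric(xi != xj)
          cnt <- cnt + 1
        } else {
          rg <- ranges[[nm]]
          num <- num + abs(xi - xj) / (rg[2] - rg[1])
          cnt <- cnt + 1
        }
      }
      d[i, j] <- num / cnt
    }
  }
  d
}

# Rao's Q by explicit double sum.
oracle_raoq <- function(d, p) {
  q <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      q <- q + p[i] * p[j] * d[i, j]
    }
  }
  q
}

# Tiny daily weather table for direct simulator tests: constant conditions.
flat_weather <- function(n_years, precip_per_day = 5, tmean = 26,
                         co2 = 380, lat = -3) {
  light <- hydrodiv:::light_index_series(lat)
  tibble::tibble(
    year = rep(seq_len(n_years), each = 365),
    doy = rep(1:365, n_years),
    month = rep(hydrodiv:::MONTH_OF_DOY, n_years),
    precip_mm = precip_per_day,
    tmean_C = tmean,
    light_index = rep(light, n_years),
    co2_ppm = co2
  )
}

# A small fixed trait table spanning the strategy space.
demo_pool <- function(n = 12, seed = 42) synth_species_pool(n, seed = seed)

# Deterministic child-seed streams for repetition studies.
seed_stream_test <- function(seed, n) hydrodiv:::seed_stream(seed, n)

# Trait sets used by the functional-diversity calculations.
FD_TRAITS_8 <- hydrodiv:::FD_TRAITS_8
FD_TRAITS_2 <- hydrodiv:::FD_TRAITS_2
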