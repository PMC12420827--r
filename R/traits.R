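#' Adaptive trait bounds
#'
#' The theoretical bounds of every adaptive trait. Continuous traits are
#' mutated and range-standardised against these bounds; the two phenology
#' traits are asymmetric binaries.
#'
#' @return A tibble with columns `trait`, `kind` (`"continuous"` or
#'   `"asymm"`), `lower`, `upper`.
#' @export
trait_bounds <- function() {
  tibble::tribble(
    ~trait,           ~kind,        ~lower, ~upper,
    "a_root",         "continuous",  0.05,   0.6,
    "a_stem",         "continuous",  0.05,   0.6,
    "a_leaf",         "continuous",  0.05,   0.6,
    "a_store",        "continuous",  0.05,   0.6,
    "a_repro",        "continuous",  0.05,   0.5,
    "seed_mass",      "continuous",  0.01,   10,
    "p50",            "continuous", -8,     -0.5,
    "evergreen",      "asymm",       0,      1,
    "light_trigger",  "asymm",       0,      1,
    "root_depth_max", "continuous",  0.5,    10,
    "root_shape",     "continuous",  0.1,    3
  )
}

# Names of the 8 traits entering functional-diversity calculations.
FD_TRAITS_8 <- c("a_store", "a_stem", "a_leaf", "a_root",
                 "p50", "evergreen", "light_trigger", "root_depth_max")
FD_TRAITS_2 <- c("p50", "root_depth_max")

#' Derived phenotype parameters from the xylem vulnerability trait
#'
#' P50 (the xylem water potential at 50 percent conductance loss) anchors a
#' hard-coded fast-risky vs slow-safe trade-off: as P50 increases (less
#' negative, more vulnerable), specific leaf area and maximum stem/leaf
#' conductivity increase while leaf longevity and wood density decrease.
#' All maps are linear between configured endpoints.
#'
#' @param p50 Vector of P50 values (MPa, negative), within bounds.
#' @param endpoints Named list of `c(at_lower_p50, at_upper_p50)` endpoint
#'   pairs for `sla` (m2 kg-1), `leaf_longevity` (days), `k_max` (relative
#'   conductivity) and `wood_density` (relative).
#' @return A tibble with columns `sla`, `leaf_longevity`, `k_stem_max`,
#'   `k_leaf_max`, `wood_density`.
#' @export
derive_phenotype <- function(p50,
                             endpoints = list(
                               sla = c(6, 24),
                               leaf_longevity = c(900, 150),
                               k_max = c(0.25, 1),
                               wood_density = c(1, 0.45)
                             )) {
  b <- trait_bounds()
  lo <- b$lower[b$trait == "p50"]
  hi <- b$upper[b$trait == "p50"]
  if (any(p50 < lo - 1e-9 | p50 > hi + 1e-9)) {
    stop(sprintf("p50 out of bounds [%g, %g]", lo, hi), call. = FALSE)
  }
  u <- (p50 - lo) / (hi - lo) # 0 at safest, 1 at most vulnerable
  lin <- function(ep) ep[1] + u * (ep[2] - ep[1])
  tibble::tibble(
    sla = lin(endpoints$sla),
    leaf_longevity = lin(endpoints$leaf_longevity),
    k_stem_max = lin(endpoints$k_max),
    k_leaf_max = lin(endpoints$k_max),
    wood_density = lin(endpoints$wood_density)
  )
}

#' Percent loss of xylem conductance
#'
#' Logistic vulnerability curve centred at P50:
#' `plc = 1 / (1 + exp(slope * (psi - p50)))`, so `psi = p50` gives exactly
#' 50 percent loss and the curve saturates at both ends. The hydraulic supply
#' multiplier used by the simulator is `1 - plc`.
#'
#' @param psi Plant water potential (MPa).
#' @param p50 Vulnerability trait (MPa).
#' @param slope Positive steepness (MPa-1), default 2.
#' @return Proportional conductance loss in `[0, 1]`.
#' @export
percent_loss_conductance <- function(psi, p50, slope = 2) {
  if (any(slope <= 0)) stop("`slope` must be positive", call. = FALSE)
  1 / (1 + exp(slope * (psi - p50)))
}

#' Per-layer root fractions from rooting traits
#'
#' A truncated-exponential rooting profile: root density decays with depth at
#' rate `root_shape` (m-1), is zero below `root_depth_max`, and integrates to
#' one over the occupied layers. `root_shape -> 0` gives a uniform profile
#' over the occupied depth.
#'
#' @param root_depth_max Maximum rooting depth (m), at most the soil depth.
#' @param root_shape Exponential decay rate (m-1), non-negative.
#' @param layer_thickness Vector of soil layer thicknesses (m), surface first.
#' @return Numeric vector of per-layer fractions summing to one.
#' @export
root_fraction_profile <- function(root_depth_max, root_shape, layer_thickness) {
  z1 <- cumsum(layer_thickness)
  z0 <- z1 - layer_thickness
  if (root_depth_max > max(z1) + 1e-9) {
    stop("root_depth_max exceeds soil depth", call. = FALSE)
  }
  top <- pmin(z1, root_depth_max)
  occ <- pmax(0, top - z0)
  w <- if (root_shape < 1e-8) {
    occ
  } else {
    ifelse(occ > 0, (exp(-root_shape * z0) - exp(-root_shape * (z0 + occ))) / root_shape, 0)
  }
  s <- sum(w)
  if (s <= 0) stop("degenerate rooting profile (no occupied layer)", call. = FALSE)
  w / s
}

#' Classify the phenological strategy of a plant
#'
#' The two asymmetric binary traits span four strategies: evergreen vs
#' deciduous leaf habit crossed with light- vs water-triggered leaf flush.
#'
#' @param evergreen 0/1 vector (1 = evergreen).
#' @param light_trigger 0/1 vector (1 = light-triggered flush).
#' @return A factor with levels `Evergreen_Light`, `Evergreen_Water`,
#'   `Deciduous_Light`, `Deciduous_Water`.
#' @export
classify_strategy <- function(evergreen, light_trigger) {
  if (!all(evergreen %in% c(0, 1)) || !all(light_trigger %in% c(0, 1))) {
    stop("phenology traits must be 0/1", call. = FALSE)
  }
  lab <- paste0(ifelse(evergreen == 1, "Evergreen", "Deciduous"), "_",
                ifelse(light_trigger == 1, "Light", "Water"))
  factor(lab, levels = c("Evergreen_Light", "Evergreen_Water",
                         "Deciduous_Light", "Deciduous_Water"))
}

# Renormalise the four growth-allocation fractions to sum to one while
# respecting their bounds (used at initialisation and after mutation).
normalize_allocation <- function(traits) {
  cols <- c("a_root", "a_stem", "a_leaf", "a_store")
  a <- as.matrix(traits[cols])
  b <- trait_bounds()
  lo <- b$lower[match(cols, b$trait)]
  hi <- b$upper[match(cols, b$trait)]
  # project each row onto the bounded simplex: entries that saturate a bound
  # are pinned there and the remainder is rescaled among the free entries
  for (r in seq_len(nrow(a))) {
    x <- pmin(pmax(a[r, ], lo), hi)
    fixed <- rep(FALSE, 4)
    for (pass in 1:6) {
      target <- 1 - sum(x[fixed])
      free <- which(!fixed)
      if (length(free) == 0 || target <= 0) break
      x[free] <- x[free] * target / sum(x[free])
      over <- free[x[free] > hi[free]]
      under <- free[x[free] < lo[free]]
      if (length(over) == 0 && length(under) == 0) break
      x[over] <- hi[over]
      x[under] <- lo[under]
      fixed[c(over, under)] <- TRUE
    }
    a[r, ] <- x
  }
  traits[cols] <- as.data.frame(a)
  traits
}

# Clip every trait to its bounds (post-mutation).
clip_traits <- function(traits) {
  b <- trait_bounds()
  for (i in seq_len(nrow(b))) {
    tr <- b$trait[i]
    if (tr %in% names(traits)) {
      traits[[tr]] <- pmin(pmax(traits[[tr]], b$lower[i]), b$upper[i])
    }
  }
  traits
}
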