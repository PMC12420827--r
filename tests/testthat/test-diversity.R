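test_that("Gower dissimilarity handles mixed types and asymmetric binaries", {
  # identical rows are at distance zero
  tr <- tibble::tibble(species = 1:2, p50 = c(-3, -3), evergreen = c(1, 1))
  d <- gower_dissimilarity(tr)
  expect_equal(d[1, 2], 0)

  # hand computation: one continuous trait at its range endpoints plus two
  # binaries both present -> (1 + 0 + 0) / 3
  tr2 <- tibble::tibble(
    species = 1:2,
    x = c(0, 1),
    b1 = c(1, 1), b2 = c(1, 1)
  )
  d2 <- gower_dissimilarity(tr2, kinds = c(x = "continuous", b1 = "asymm", b2 = "asymm"),
                            ranges = list(x = c(0, 1)))
  expect_equal(d2[1, 2], 1 / 3)

  # double-zero exclusion: a shared absence drops the trait from the average
  tr3 <- tibble::tibble(species = 1:2, x = c(0.2, 0.7), b1 = c(0, 0))
  d3 <- gower_dissimilarity(tr3, kinds = c(x = "continuous", b1 = "asymm"),
                            ranges = list(x = c(0, 1)))
  expect_equal(d3[1, 2], 0.5) # only the continuous trait contributes

  # a pair with no contributing trait is an error
  tr4 <- tibble::tibble(species = 1:2, b1 = c(0, 0))
  expect_error(gower_dissimilarity(tr4, kinds = c(b1 = "asymm")), "zero contributing")
})

test_that("Gower matches an independent double-loop implementation", {
  pool <- demo_pool(20, seed = 99)
  tr <- pool[c("p50", "root_depth_max", "a_store", "evergreen", "light_trigger")]
  b <- trait_bounds()
  kinds <- setNames(b$kind[match(names(tr), b$trait)], names(tr))
  ranges <- setNames(lapply(names(tr), function(nm) {
    c(b$lower[b$trait == nm], b$upper[b$trait == nm])
  }), names(tr))
  d_pkg <- gower_dissimilarity(dplyr::bind_cols(tibble::tibble(species = 1:20), tr))
  d_orc <- oracle_gower(tr, kinds, ranges)
  expect_equal(unname(d_pkg), d_orc, tolerance = 1e-12)
  expect_true(all(d_pkg >= 0 & d_pkg <= 1))
  expect_true(isSymmetric(unname(d_pkg)))

  # cross-check against the field-standard mixed-type implementation
  df <- as.data.frame(tr)
  df$evergreen <- factor(df$evergreen, levels = c(0, 1))
  df$light_trigger <- factor(df$light_trigger, levels = c(0, 1))
  d_daisy <- as.matrix(cluster::daisy(df, metric = "gower",
                                      type = list(asymm = c(4, 5))))
  # daisy standardises continuous traits by the observed range
  d_pkg_obs <- gower_dissimilarity(
    dplyr::bind_cols(tibble::tibble(species = 1:20), tr),
    ranges = lapply(tr, range)
  )
  expect_equal(unname(d_pkg_obs), unname(d_daisy), tolerance = 1e-10)
})

test_that("Rao's quadratic entropy matches the double sum and its invariances", {
  # two species at dissimilarity 0.6 with equal abundance
  d <- matrix(c(0, 0.6, 0.6, 0), 2)
  expect_equal(rao_q(d, c(0.5, 0.5)), 0.3)
  # monoculture
  expect_equal(rao_q(d, c(1, 0)), 0)
  # brute-force oracle on a random community
  pool <- demo_pool(15, seed = 3)
  dm <- gower_dissimilarity(pool[c("species", FD_TRAITS_8)])
  set.seed(4)
  p <- runif(15); p <- p / sum(p)
  expect_equal(rao_q(dm, p), oracle_raoq(dm, p), tolerance = 1e-12)
  expect_lte(rao_q(dm, p), max(dm))

  # splitting one species into two identical halves leaves RaoQ unchanged
  dm2 <- rbind(cbind(dm, dm[, 1]), c(dm[1, ], 0))
  p2 <- c(p[1] / 2, p[-1], p[1] / 2)
  expect_equal(rao_q(dm2, p2), rao_q(dm, p), tolerance = 1e-12)

  expect_error(rao_q(dm, rep(0.5, 15)), "sum to one")
  expect_equal(rao_q(dm, p * 7, normalize = TRUE), rao_q(dm, p))
})

test_that("8-trait and 2-trait modes agree on restricted tables", {
  pool <- demo_pool(10, seed = 12)
  d2 <- gower_dissimilarity(pool[c("species", FD_TRAITS_2)])
  d2b <- gower_dissimilarity(pool[c("species", FD_TRAITS_8)][c("species", "p50", "root_depth_max")])
  expect_equal(d2, d2b)
})

test_that("community-weighted means are abundance-weighted sums", {
  tr <- tibble::tibble(species = 1:2, x = c(1, 3), p50 = c(-2, -4))
  cwm <- community_weighted_mean(tr, c(0.5, 0.5))
  expect_equal(cwm$x, 2)
  expect_equal(cwm$p50, -3)
  expect_equal(cwm$cwm_sla, derive_phenotype(-3)$sla)
  # monoculture returns that species' traits
  cwm1 <- community_weighted_mean(tr, c(1, 0))
  expect_equal(cwm1$x, 1)
  # brute force on a random table
  pool <- demo_pool(8, seed = 5)
  set.seed(6)
  p <- runif(8); p <- p / sum(p)
  cwm2 <- community_weighted_mean(pool[c("p50", "a_store")], p)
  expect_equal(cwm2$a_store, sum(p * pool$a_store), tolerance = 1e-12)
})

test_that("trait-space PCA recovers the planted hydraulic axis", {
  pool <- synth_species_pool(96, axis_strength = 0.9, seed = 21)
  pc <- pca_trait_space(pool[c("species", FD_TRAITS_8)])
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-12)
  expect_gte(sum(pc$variance_fraction[1:2]), 0.49)
  # sign convention: rooting depth loads positively on its dominant axis
  ld <- as.matrix(pc$loadings[-1])
  rd <- ld[pc$loadings$trait == "root_depth_max", ]
  expect_gte(rd[which.max(abs(rd))], 0)

  # scores reproduce an independent eigendecomposition of the correlation matrix
  X <- scale(as.matrix(pool[FD_TRAITS_8]))
  eig <- eigen(stats::cor(as.matrix(pool[FD_TRAITS_8])))
  expect_equal(pc$variance_fraction, eig$values / sum(eig$values), tolerance = 1e-9)
  sc <- as.matrix(pc$scores[c("PC1", "PC2")])
  sc_eig <- X %*% eig$vectors[, 1:2]
  for (j in 1:2) {
    expect_equal(abs(stats::cor(sc[, j], sc_eig[, j])), 1, tolerance = 1e-9)
  }

  # zero-variance columns are dropped with a warning
  pool$flat <- 1
  expect_warning(pca_trait_space(pool[c("species", "p50", "root_depth_max", "flat")]),
                 "zero-variance")
})

test_that("transpiration stability is mean over sd of annual totals", {
  out <- transpiration_stability(c(1, 2, 3))
  expect_equal(out$mean, 2)
  expect_equal(out$sd, 1)
  expect_equal(out$stability, 2)

  expect_warning(cst <- transpiration_stability(c(2, 2, 2)), "constant")
  expect_equal(cst$stability, Inf)

  # daily series aggregate by year first
  daily <- tibble::tibble(year = rep(1:3, each = 365),
                          transpiration_mm = rep(c(2, 3, 4) / 365, each = 365))
  agg <- transpiration_stability(daily)
  expect_equal(agg$mean, 3, tolerance = 1e-9)

  # two-pass check on random data
  set.seed(10)
  x <- runif(50, 800, 1200)
  st <- transpiration_stability(x)
  expect_equal(st$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)), tolerance = 1e-12)
})

test_that("k-medoids pooling returns per-cluster means and abundances", {
  pool <- synth_species_pool(60, seed = 31)
  cl <- cluster_species_pool(pool[c("species", FD_TRAITS_8)], k = 5, seed = 9)
  expect_equal(nrow(cl$pool), 5)
  expect_equal(sum(cl$abundance), 60)
  expect_equal(length(cl$cluster), 60)
  # medoid means actually average their members
  m1 <- colMeans(pool[cl$cluster == 1, "p50"])
  expect_equal(cl$pool$p50[1], unname(m1), tolerance = 1e-12)
})
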