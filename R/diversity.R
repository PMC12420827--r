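#' Gower dissimilarity with asymmetric binary traits
#'
#' Mixed-type, range-standardised dissimilarity between species. Continuous
#' traits contribute `|x_i - x_j| / range`; asymmetric binary traits
#' contribute 1 when the states differ, 0 when both are present (1/1), and
#' are excluded from the average when both are absent (0/0, Jaccard-style).
#' The pairwise dissimilarity is the mean over contributing traits. Note
#' that with double-zero exclusion the result need not satisfy the triangle
#' inequality.
#'
#' @param traits A data frame, rows = species, columns = traits. Non-trait
#'   columns (e.g. `species`) are ignored if named in `id_cols`.
#' @param kinds Named character vector mapping trait names to `"continuous"`
#'   or `"asymm"`. Defaults to the declarations in [trait_bounds()] for known
#'   trait names and `"continuous"` otherwise.
#' @param ranges Named list of `c(lower, upper)` standardisation ranges for
#'   continuous traits. Defaults to the theoretical bounds in
#'   [trait_bounds()] for known traits and the observed range otherwise.
#' @param id_cols Column names to drop before computing (default
#'   `"species"`).
#' @return A symmetric matrix of dissimilarities in `[0, 1]` with zero
#'   diagonal; row/column names follow the `species` column when present.
#' @export
gower_dissimilarity <- function(traits, kinds = NULL, ranges = NULL,
                                id_cols = "species") {
  labels <- if ("species" %in% names(traits)) as.character(traits$species) else NULL
  tr <- traits[setdiff(names(traits), id_cols)]
  if (ncol(tr) < 1) stop("need at least one trait column", call. = FALSE)
  if (anyNA(tr)) stop("trait table contains missing values", call. = FALSE)
  b <- trait_bounds()
  n <- nrow(tr)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (nm in names(tr)) {
    x <- tr[[nm]]
    kind <- kinds[nm] %||% NULL
    if (is.null(kind) || is.na(kind)) {
      kind <- if (nm %in% b$trait) b$kind[b$trait == nm] else "continuous"
    }
    if (kind == "asymm") {
      if (!all(x %in% c(0, 1))) {
        stop(sprintf("asymmetric binary trait '%s' must be 0/1", nm), call. = FALSE)
      }
      both_zero <- outer(x == 0, x == 0, "&")
      differ <- outer(x, x, "!=") * 1
      num <- num + ifelse(both_zero, 0, differ)
      den <- den + !both_zero
    } else {
      rg <- ranges[[nm]] %||% NULL
      if (is.null(rg)) {
        rg <- if (nm %in% b$trait) c(b$lower[b$trait == nm], b$upper[b$trait == nm]) else range(x)
      }
      width <- rg[2] - rg[1]
      if (width <= 0) stop(sprintf("trait '%s' has non-positive range width", nm), call. = FALSE)
      num <- num + abs(outer(x, x, "-")) / width
      den <- den + 1
    }
  }
  if (any(den[upper.tri(den)] == 0)) {
    stop("some species pair has zero contributing traits", call. = FALSE)
  }
  d <- num / pmax(den, 1)
  diag(d) <- 0
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  d
}

#' Rao's quadratic entropy
#'
#' The abundance-weighted expected dissimilarity between two randomly drawn
#' individuals: `RaoQ = sum_i sum_j p_i p_j d_ij`. A monoculture has RaoQ 0.
#'
#' @param d Symmetric dissimilarity matrix (e.g. from
#'   [gower_dissimilarity()]).
#' @param p Relative abundances, non-negative and summing to one; raw counts
#'   are accepted and normalised when `normalize = TRUE`.
#' @param normalize If `TRUE` (default `FALSE`), normalise `p` to sum to one
#'   instead of erroring on unnormalised input.
#' @return A non-negative scalar.
#' @export
rao_q <- function(d, p, normalize = FALSE) {
  if (length(p) != nrow(d)) stop("`p` and `d` are not conformable", call. = FALSE)
  if (any(p < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (normalize) {
    s <- sum(p)
    if (s <= 0) stop("abundances sum to zero", call. = FALSE)
    p <- p / s
  } else if (abs(sum(p) - 1) > 1e-8) {
    stop("`p` must sum to one (or pass normalize = TRUE)", call. = FALSE)
  }
  drop(t(p) %*% d %*% p)
}

#' Community-weighted trait means
#'
#' Abundance-weighted mean of every trait column; when a `p50` column is
#' present, the community-mean specific leaf area implied by the P50
#' trade-off map ([derive_phenotype()]) is appended as `cwm_sla`.
#'
#' @param traits Species-by-trait data frame (a `species` column is ignored).
#' @param p Relative abundances summing to one.
#' @return A one-row tibble of community-weighted means.
#' @export
community_weighted_mean <- function(traits, p) {
  tr <- traits[setdiff(names(traits), "species")]
  if (length(p) != nrow(tr)) stop("`p` and `traits` are not conformable", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("`p` must sum to one", call. = FALSE)
  cwm <- as.data.frame(as.list(colSums(as.matrix(tr) * p)))
  out <- tibble::as_tibble(cwm)
  if ("p50" %in% names(out)) {
    out$cwm_sla <- derive_phenotype(out$p50)$sla
  }
  out
}

#' Trait-space principal component analysis
#'
#' Column-standardised PCA of a species trait table (binary traits coded
#' 0/1). Zero-variance columns are dropped with a warning. Axis signs follow
#' a deterministic convention: the axis on which `root_depth_max` loads most
#' strongly is oriented so that loading is positive; every other axis is
#' oriented so its largest-magnitude loading is positive.
#'
#' @param traits Species-by-trait data frame (`species` column optional).
#' @return A list of class `trait_pca` with `scores` (tibble), `loadings`
#'   (tibble, one row per trait), and `variance_fraction`.
#' @export
pca_trait_space <- function(traits) {
  labels <- if ("species" %in% names(traits)) traits$species else seq_len(nrow(traits))
  tr <- traits[setdiff(names(traits), "species")]
  if (nrow(tr) < 3 || ncol(tr) < 2) {
    stop("need at least 3 species and 2 traits", call. = FALSE)
  }
  v <- vapply(tr, var, numeric(1))
  if (any(v == 0)) {
    warning(sprintf("dropping zero-variance trait(s): %s",
                    paste(names(tr)[v == 0], collapse = ", ")))
    tr <- tr[v > 0]
  }
  pc <- prcomp(as.matrix(tr), center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  flip <- rep(1, ncol(rot))
  anchor_pc <- if ("root_depth_max" %in% rownames(rot)) {
    which.max(abs(rot["root_depth_max", ]))
  } else {
    0L
  }
  for (j in seq_len(ncol(rot))) {
    ld <- if (j == anchor_pc) rot["root_depth_max", j] else rot[which.max(abs(rot[, j])), j]
    if (ld < 0) flip[j] <- -1
  }
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = tibble::tibble(species = labels, tibble::as_tibble(scores)),
      loadings = tibble::tibble(trait = rownames(rot), tibble::as_tibble(rot)),
      variance_fraction = vf
    ),
    class = "trait_pca"
  )
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("<trait_pca> variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction[1:min(4, length(x$variance_fraction))]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Transpiration stability
#'
#' Mean, standard deviation and stability (mean / sd, the inverse
#' coefficient of variation) of annual transpiration. Daily series with a
#' `year` column are aggregated to annual totals first.
#'
#' @param x Either a numeric vector of annual transpiration values or a data
#'   frame with columns `year` and `transpiration_mm` (daily or annual).
#' @return A one-row tibble with `mean`, `sd`, `stability`. A constant
#'   series (sd 0) yields `stability = Inf` with a warning.
#' @export
transpiration_stability <- function(x) {
  if (is.data.frame(x)) {
    assert_cols(x, c("year", "transpiration_mm"), "transpiration series")
    x <- tapply(x$transpiration_mm, x$year, sum)
  }
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 annual values", call. = FALSE)
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    warning("constant transpiration series: stability reported as Inf")
    return(tibble::tibble(mean = m, sd = 0, stability = Inf))
  }
  tibble::tibble(mean = m, sd = s, stability = m / s)
}

#' Pool species by k-medoids partitioning of trait space
#'
#' Standardises the continuous traits and partitions individuals (or
#' species) into `k` clusters with a seeded k-medoids algorithm
#' (`cluster::clara` for large inputs, `cluster::pam` otherwise). Cluster
#' trait means form the pooled species-trait table; cluster sizes give
#' abundances.
#'
#' @param traits Individual- or species-level trait data frame.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return A list with `pool` (tibble of cluster mean traits, one row per
#'   cluster, with `species = 1..k`), `abundance` (counts per cluster) and
#'   `cluster` (assignment vector).
#' @export
cluster_species_pool <- function(traits, k, seed) {
  tr <- traits[setdiff(names(traits), "species")]
  if (k >= nrow(tr)) stop("`k` must be smaller than the number of rows", call. = FALSE)
  z <- scale(as.matrix(tr))
  z[, attr(z, "scaled:scale") == 0] <- 0
  cl <- with_seed(seed, {
    if (nrow(z) > 2000) {
      cluster::clara(z, k, samples = 20, pamLike = TRUE)$clustering
    } else {
      cluster::pam(z, k, cluster.only = TRUE)
    }
  })
  pool <- dplyr::summarise(dplyr::group_by(dplyr::mutate(tr, .cl = cl), .data$.cl),
                           dplyr::across(dplyr::everything(), mean), .groups = "drop")
  pool <- dplyr::rename(pool, species = ".cl")
  list(pool = pool, abundance = as.integer(table(cl)), cluster = cl)
}
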