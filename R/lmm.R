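# Continental-scale mixed-effects analysis: percentage biomass change
# regressed on baseline precipitation, diversity, precipitation reduction and
# scenario factors, with a site random intercept, AIC-guided pruning of
# interaction terms, Nakagawa R2, and fixed-effect prediction grids.

LMM_CONTINUOUS <- c("precip_1990", "raoq", "precip_change")
LMM_FACTORS <- c("rcp", "co2")

#' Fit the continental diversity-drought mixed-effects model
#'
#' Fits `pct_change ~ (precip_1990 + raoq + precip_change + rcp + co2)^2 +
#' (1 | site)` with all continuous covariates z-standardised and factors
#' dummy-coded (reference levels `rcp45` and `rising` CO2). Starting from
#' the model with all two-way interactions, interaction terms are removed
#' backwards one at a time, always dropping the term whose removal lowers
#' AIC the most (ML fits during selection), until no removal lowers AIC; the
#' final model is refitted with REML. Marginal and conditional R2 follow
#' Nakagawa & Schielzeth.
#'
#' @param data A site table with columns `pct_change` (% AGB change),
#'   `precip_1990` (mm), `raoq`, `precip_change` (mm reduction by the end of
#'   the scenario), `rcp` (factor), `co2` (factor), `site`.
#' @param prune If `FALSE`, keep the saturated two-way interaction model.
#' @return An object of class `diversity_lmm` with the fitted `lme4` model,
#'   the scaling used, the AIC elimination path, and R2 values.
#' @export
fit_lmm <- function(data, prune = TRUE) {
  assert_cols(data, c("pct_change", LMM_CONTINUOUS, LMM_FACTORS, "site"),
              "continental site table")
  df <- tibble::as_tibble(data)
  df$rcp <- stats::relevel(factor(df$rcp), ref = intersect(c("rcp45", levels(factor(df$rcp))[1]), levels(factor(df$rcp)))[1])
  if ("rising" %in% unique(as.character(df$co2))) {
    df$co2 <- stats::relevel(factor(df$co2), ref = "rising")
  } else {
    df$co2 <- factor(df$co2)
  }
  if (min(table(df$site)) < 2) stop("need at least 2 observations per site", call. = FALSE)
  centers <- vapply(df[LMM_CONTINUOUS], mean, numeric(1))
  scales <- vapply(df[LMM_CONTINUOUS], sd, numeric(1))
  if (any(scales == 0)) stop("a continuous covariate is constant", call. = FALSE)
  for (v in LMM_CONTINUOUS) df[[v]] <- (df[[v]] - centers[v]) / scales[v]

  main <- paste(c(LMM_CONTINUOUS, LMM_FACTORS), collapse = " + ")
  inter <- utils::combn(c(LMM_CONTINUOUS, LMM_FACTORS), 2,
                        function(p) paste(p, collapse = ":"))
  # drop interactions involving a single-level factor
  ok_term <- vapply(inter, function(tm) {
    vars <- strsplit(tm, ":")[[1]]
    all(vapply(vars, function(v) {
      !(v %in% LMM_FACTORS) || nlevels(df[[v]]) >= 2
    }, logical(1)))
  }, logical(1))
  inter <- inter[ok_term]
  if (any(vapply(LMM_FACTORS, function(v) nlevels(df[[v]]) < 2, logical(1)))) {
    main <- paste(c(LMM_CONTINUOUS,
                    LMM_FACTORS[vapply(LMM_FACTORS, function(v) nlevels(df[[v]]) >= 2, logical(1))]),
                  collapse = " + ")
  }

  build_formula <- function(terms) {
    rhs <- paste(c(main, terms), collapse = " + ")
    as.formula(paste("pct_change ~", rhs, "+ (1 | site)"))
  }
  fit_ml <- function(terms) {
    suppressMessages(lme4::lmer(build_formula(terms), data = df, REML = FALSE))
  }
  current <- inter
  path <- tibble::tibble(step = 0L, dropped = NA_character_,
                         aic = AIC(fit_ml(current)))
  if (prune && length(current) > 0) {
    repeat {
      base_aic <- path$aic[nrow(path)]
      cand <- vapply(seq_along(current), function(i) AIC(fit_ml(current[-i])), numeric(1))
      best <- which.min(cand)
      if (length(cand) == 0 || cand[best] >= base_aic) break
      path <- dplyr::bind_rows(path, tibble::tibble(
        step = nrow(path), dropped = current[best], aic = cand[best]))
      current <- current[-best]
      if (length(current) == 0) break
    }
  }
  model <- suppressMessages(lme4::lmer(build_formula(current), data = df, REML = TRUE))
  if (lme4::isSingular(model)) {
    warning("singular random-effect fit; site variance is at or near zero")
  }
  r2 <- nakagawa_r2(model)
  structure(
    list(
      model = model,
      interactions = current,
      aic_path = path,
      centers = centers, scales = scales,
      data = df,
      r2 = r2,
      n = nrow(df)
    ),
    class = "diversity_lmm"
  )
}

# Nakagawa & Schielzeth R2 for a Gaussian LMM with identity link.
nakagawa_r2 <- function(model) {
  fx <- lme4::fixef(model)
  X <- model.matrix(model)
  var_f <- var(as.numeric(X %*% fx))
  vc <- lme4::VarCorr(model)
  var_r <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' @export
print.diversity_lmm <- function(x, ...) {
  cat(sprintf("<diversity_lmm> n = %d, %d interaction term(s) retained\n",
              x$n, length(x$interactions)))
  cat(sprintf("  marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2["marginal"], x$r2["conditional"]))
  invisible(x)
}

#' @rdname fit_lmm
#' @param x A `diversity_lmm` object.
#' @param ... Unused.
#' @export
tidy.diversity_lmm <- function(x, ...) {
  fx <- lme4::fixef(x$model)
  se <- sqrt(diag(as.matrix(vcov(x$model))))
  tibble::tibble(
    term = names(fx),
    estimate = unname(fx),
    std.error = unname(se),
    conf.low = unname(fx - 1.96 * se),
    conf.high = unname(fx + 1.96 * se)
  )
}

#' @rdname fit_lmm
#' @export
glance.diversity_lmm <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    n_sites = length(unique(x$data$site)),
    r2_marginal = unname(x$r2["marginal"]),
    r2_conditional = unname(x$r2["conditional"]),
    aic = AIC(x$model),
    interactions = length(x$interactions)
  )
}

# Fixed-effect predictions with normal-approximation CIs on new data given
# on the original (unscaled) covariate scale.
predict_fixed <- function(obj, newdata, level = 0.95) {
  nd <- tibble::as_tibble(newdata)
  for (v in LMM_CONTINUOUS) nd[[v]] <- (nd[[v]] - obj$centers[v]) / obj$scales[v]
  nd$rcp <- factor(nd$rcp, levels = levels(obj$data$rcp))
  nd$co2 <- factor(nd$co2, levels = levels(obj$data$co2))
  nd$pct_change <- 0
  form <- stats::formula(obj$model, fixed.only = TRUE)
  X <- model.matrix(stats::delete.response(stats::terms(form)), nd)
  fx <- lme4::fixef(obj$model)
  X <- X[, names(fx), drop = FALSE]
  pred <- as.numeric(X %*% fx)
  se <- sqrt(rowSums((X %*% as.matrix(vcov(obj$model))) * X))
  z <- qnorm(1 - (1 - level) / 2)
  out <- tibble::as_tibble(newdata)
  out$pred <- pred
  out$conf.low <- pred - z * se
  out$conf.high <- pred + z * se
  out
}

#' Predicted diversity effect across precipitation reduction levels
#'
#' Evaluates the fitted fixed-effects surface on a grid: baseline
#' precipitation held at `baseline` (mm), precipitation reduction at each
#' value of `reductions`, and diversity spanning `raoq_range`. The diversity
#' effect per reduction level is the difference in predicted percentage
#' biomass change between the high- and low-diversity ends (positive =
#' diversity mitigates loss).
#'
#' @param obj A `diversity_lmm` fit.
#' @param baseline Baseline annual precipitation (mm), default 2500.
#' @param reductions Precipitation reductions (mm) by scenario end, default
#'   `c(750, 1000, 1250)` (30, 40, 50 percent of the 2500 mm baseline).
#' @param raoq_range Diversity endpoints; default the observed range.
#' @param rcp,co2 Factor levels at which to predict (defaults: reference
#'   levels).
#' @param n_grid Number of diversity grid points per curve.
#' @return A list with `curves` (tibble of predictions with 95 percent CIs)
#'   and `effects` (tibble: one row per reduction level with the diversity
#'   effect in percentage points of biomass change).
#' @export
predict_diversity_effect <- function(obj, baseline = 2500,
                                     reductions = c(750, 1000, 1250),
                                     raoq_range = NULL,
                                     rcp = NULL, co2 = NULL, n_grid = 25) {
  stopifnot(inherits(obj, "diversity_lmm"))
  obs_raoq <- obj$data$raoq * obj$scales["raoq"] + obj$centers["raoq"]
  raoq_range <- raoq_range %||% range(obs_raoq)
  if (raoq_range[1] < min(obs_raoq) - 1e-9 || raoq_range[2] > max(obs_raoq) + 1e-9) {
    warning("diversity grid extends beyond the observed RaoQ range")
  }
  rcp <- rcp %||% levels(obj$data$rcp)[1]
  co2 <- co2 %||% levels(obj$data$co2)[1]
  grid <- tidyr::expand_grid(
    precip_1990 = baseline,
    precip_change = reductions,
    raoq = seq(raoq_range[1], raoq_range[2], length.out = n_grid),
    rcp = rcp, co2 = co2
  )
  curves <- predict_fixed(obj, grid)
  effects <- dplyr::summarise(
    dplyr::group_by(curves, .data$precip_change),
    reduction_pct = reduction_percent(baseline, .data$precip_change[1]),
    pred_low_div = .data$pred[which.min(.data$raoq)],
    pred_high_div = .data$pred[which.max(.data$raoq)],
    diversity_effect = .data$pred_high_div - .data$pred_low_div,
    .groups = "drop"
  )
  list(curves = curves, effects = effects)
}

#' Filter continental sites by baseline biomass and precipitation drop
#'
#' Keeps rows whose 1990 above-ground biomass lies inside `agb_range`
#' (inclusive) and whose precipitation reduction by scenario end is at least
#' `min_precip_drop` (inclusive).
#'
#' @param site_table Data frame with columns `agb_1990` (t/ha) and
#'   `precip_change` (mm).
#' @param agb_range Inclusive biomass window, default `c(150, 200)` t/ha.
#' @param min_precip_drop Minimum precipitation reduction, default 250 mm.
#' @return The filtered tibble.
#' @export
filter_sites <- function(site_table, agb_range = c(150, 200),
                         min_precip_drop = 250) {
  assert_cols(site_table, c("agb_1990", "precip_change"), "site table")
  dplyr::filter(
    tibble::as_tibble(site_table),
    .data$agb_1990 >= agb_range[1], .data$agb_1990 <= agb_range[2],
    .data$precip_change >= min_precip_drop
  )
}
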