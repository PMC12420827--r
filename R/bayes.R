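# Heteroscedastic Bayesian regression of drought biomass loss on functional
# diversity, with Bayes-factor model comparison via bridge sampling.

# Log joint density (likelihood + priors). H1 has mean and log-sd linear in
# the diversity covariate; H0 is intercept-only in both parts.
hetero_log_post <- function(theta, y, x, null_model = FALSE) {
  if (null_model) {
    alpha <- theta[1]; gamma <- theta[2]
    mu <- alpha
    logsig <- gamma
    lp <- dnorm(alpha, 0, 10, log = TRUE) + dnorm(gamma, 0, 1, log = TRUE)
  } else {
    alpha <- theta[1]; beta <- theta[2]; gamma <- theta[3]; delta <- theta[4]
    mu <- alpha + beta * x
    logsig <- gamma + delta * x
    lp <- dnorm(alpha, 0, 10, log = TRUE) + dnorm(beta, 0, 10, log = TRUE) +
      dnorm(gamma, 0, 1, log = TRUE) + dnorm(delta, 0, 1, log = TRUE)
  }
  sig <- exp(logsig)
  ll <- sum(dnorm(y, mu, sig, log = TRUE))
  if (!is.finite(ll)) ll <- -Inf
  ll + lp
}

# One adaptive random-walk Metropolis chain. During warmup the proposal
# covariance is re-estimated from the recent chain history (scaled
# 2.38^2/d) and a global step-size factor is tuned towards a 30 percent
# acceptance rate; after warmup the proposal is frozen so the sampling
# phase is a valid Markov chain.
run_mh_chain <- function(log_post, init, iter, warmup, init_scale = NULL,
                         adapt_every = 50) {
  d <- length(init)
  theta <- init
  lp <- log_post(theta)
  draws <- matrix(NA_real_, iter - warmup, d)
  hist <- matrix(NA_real_, warmup, d)
  sc <- init_scale %||% (0.1 * pmax(abs(init), 0.5))
  prop_chol <- diag(sc, d)
  scale_fac <- 2.38^2 / d
  step <- 1
  n_acc <- 0L
  acc_win <- 0L
  for (i in seq_len(iter)) {
    prop <- theta + step * drop(rnorm(d) %*% prop_chol)
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
      theta <- prop
      lp <- lp_prop
      if (i > warmup) n_acc <- n_acc + 1L else acc_win <- acc_win + 1L
    }
    if (i <= warmup) {
      hist[i, ] <- theta
      if (i %% adapt_every == 0) {
        # step-size tuning towards ~0.3 acceptance
        rate <- acc_win / adapt_every
        step <- step * exp(rate - 0.3)
        acc_win <- 0L
        # covariance adaptation from the recent history
        lo <- max(1, i - 10 * adapt_every)
        if (i - lo > 2 * d) {
          cv <- stats::cov(hist[lo:i, , drop = FALSE])
          cv <- cv * scale_fac + diag(1e-10, d)
          ch <- tryCatch(chol(cv), error = function(e) NULL)
          if (!is.null(ch)) {
            prop_chol <- ch
            step <- 1
          }
        }
      }
    } else {
      draws[i - warmup, ] <- theta
    }
  }
  list(draws = draws, accept_rate = n_acc / (iter - warmup))
}

# Split-R-hat (Gelman et al.) for a draws array [iter, chain].
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  b <- half * var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Fit the heteroscedastic Bayesian diversity-resistance model
#'
#' Models percentage biomass loss as Gaussian with both the mean and the
#' residual standard deviation depending on functional diversity (RaoQ):
#' `mu_i = alpha + beta * raoq_i`, `log(sigma_i) = gamma + delta * raoq_i`.
#' Priors are weakly informative: `alpha, beta ~ N(0, 10)`,
#' `gamma, delta ~ N(0, 1)`. Posterior draws come from four adaptive
#' random-walk Metropolis chains (2000 iterations each, 1000 warmup, by
#' default); convergence is checked with split-R-hat.
#'
#' @param data A data frame holding the response and the diversity covariate.
#' @param response,diversity Unquoted column names of percentage biomass loss
#'   and RaoQ (defaults `bm_loss`, `raoq`).
#' @param chains,iter,warmup Sampler settings (defaults 4, 2000, 1000).
#' @param seed Integer seed (required).
#' @param null_model If `TRUE`, fit the intercept-only model (H0) in both the
#'   mean and the log-sd part.
#' @return An object of class `hetero_bayes` with posterior `draws` (tibble:
#'   `chain`, `iter`, one column per parameter), `rhat`, `accept_rate`, the
#'   data used, and the model form.
#' @export
fit_hetero_bayes <- function(data, response = bm_loss, diversity = raoq,
                             chains = 4, iter = 2000, warmup = 1000,
                             seed, null_model = FALSE) {
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  x <- rlang::eval_tidy(rlang::enquo(diversity), data)
  keep <- complete.cases(y, x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 20) stop("need at least 20 observations", call. = FALSE)
  if (!null_model && var(x) == 0) {
    stop("diversity covariate is constant: slope not identifiable", call. = FALSE)
  }
  lpost <- function(theta) hetero_log_post(theta, y, x, null_model)
  d <- if (null_model) 2L else 4L
  par_names <- if (null_model) c("alpha", "gamma") else c("alpha", "beta", "gamma", "delta")

  res <- with_seed(seed, {
    if (null_model) {
      base_init <- c(mean(y), log(sd(y)))
      init_scale <- c(sd(y) / sqrt(n), 1 / sqrt(2 * n))
    } else {
      cf <- stats::lm.fit(cbind(1, x), y)$coefficients
      base_init <- c(cf[1], cf[2], log(sd(y)), 0)
      se_b <- sd(y) / (sqrt(n) * sd(x))
      init_scale <- c(sd(y) / sqrt(n), se_b, 1 / sqrt(2 * n), 1 / (sqrt(2 * n) * sd(x)))
    }
    lapply(seq_len(chains), function(ch) {
      init <- base_init + rnorm(d, 0, 2 * init_scale)
      run_mh_chain(lpost, init, iter, warmup, init_scale = init_scale)
    })
  })
  draw_arr <- lapply(res, `[[`, "draws")
  rhat <- vapply(seq_len(d), function(j) {
    split_rhat(vapply(draw_arr, function(m) m[, j], numeric(iter - warmup)))
  }, numeric(1))
  names(rhat) <- par_names
  if (any(rhat > 1.01)) {
    warning(sprintf("split-R-hat above 1.01 for: %s",
                    paste(par_names[rhat > 1.01], collapse = ", ")))
  }
  draws <- do.call(rbind, draw_arr)
  colnames(draws) <- par_names
  draws_tbl <- tibble::tibble(
    chain = rep(seq_len(chains), each = iter - warmup),
    iter = rep(seq_len(iter - warmup), chains),
    tibble::as_tibble(draws)
  )
  structure(
    list(
      draws = draws_tbl,
      rhat = rhat,
      accept_rate = vapply(res, `[[`, numeric(1), "accept_rate"),
      data = tibble::tibble(bm_loss = y, raoq = x),
      null_model = null_model,
      settings = list(chains = chains, iter = iter, warmup = warmup, seed = seed),
      n = n
    ),
    class = "hetero_bayes"
  )
}

#' @export
print.hetero_bayes <- function(x, ...) {
  cat(sprintf("<hetero_bayes> %s, n = %d, %d chains x %d draws\n",
              if (x$null_model) "H0 (intercept-only)" else "H1 (mean and log-sd ~ RaoQ)",
              x$n, x$settings$chains, x$settings$iter - x$settings$warmup))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname fit_hetero_bayes
#' @param x A `hetero_bayes` object.
#' @param ... Unused.
#' @export
tidy.hetero_bayes <- function(x, ...) {
  par_names <- setdiff(names(x$draws), c("chain", "iter"))
  purrr::map_dfr(par_names, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(
      term = p,
      estimate = median(v),
      std.error = sd(v),
      conf.low = unname(quantile(v, 0.025)),
      conf.high = unname(quantile(v, 0.975))
    )
  })
}

#' @rdname fit_hetero_bayes
#' @export
glance.hetero_bayes <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    chains = x$settings$chains,
    draws = nrow(x$draws),
    max_rhat = max(x$rhat),
    min_accept = min(x$accept_rate)
  )
}

# Posterior draws as a plain matrix.
draw_matrix <- function(fit) {
  as.matrix(fit$draws[setdiff(names(fit$draws), c("chain", "iter"))])
}

#' Posterior predictive summary over the observed diversity range
#'
#' @param fit A `hetero_bayes` fit.
#' @param raoq Grid of diversity values (default 50 points over the observed
#'   range).
#' @return A tibble with posterior median and 95 percent credible bounds of
#'   the mean response and of the residual sd at each grid point.
#' @export
posterior_predictive_band <- function(fit, raoq = NULL) {
  if (is.null(raoq)) {
    raoq <- seq(min(fit$data$raoq), max(fit$data$raoq), length.out = 50)
  }
  dm <- draw_matrix(fit)
  purrr::map_dfr(raoq, function(x0) {
    if (fit$null_model) {
      mu <- dm[, "alpha"]; sig <- exp(dm[, "gamma"])
    } else {
      mu <- dm[, "alpha"] + dm[, "beta"] * x0
      sig <- exp(dm[, "gamma"] + dm[, "delta"] * x0)
    }
    tibble::tibble(
      raoq = x0,
      mu = median(mu),
      mu_lo = unname(quantile(mu, 0.025)), mu_hi = unname(quantile(mu, 0.975)),
      sigma = median(sig),
      sigma_lo = unname(quantile(sig, 0.025)), sigma_hi = unname(quantile(sig, 0.975))
    )
  })
}

# Log marginal likelihood by bridge sampling (Meng & Wong iterative
# estimator with a moment-matched multivariate normal proposal, computed in
# log space for stability). Returns the estimate and its approximate
# relative standard error.
bridge_log_ml <- function(fit, n_prop = NULL, seed = 1, maxit = 200, tol = 1e-10) {
  dm <- draw_matrix(fit)
  n1 <- nrow(dm)
  n2 <- n_prop %||% n1
  mu <- colMeans(dm)
  cv <- stats::cov(dm) + diag(1e-10, ncol(dm))
  ch <- chol(cv)
  lpost <- function(th) hetero_log_post(th, fit$data$bm_loss, fit$data$raoq, fit$null_model)
  ldprop <- function(m) {
    z <- forwardsolve(t(ch), t(m) - mu)
    -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * ncol(dm) * log(2 * pi)
  }
  prop <- with_seed(seed, {
    matrix(rnorm(n2 * ncol(dm)), n2) %*% ch
  })
  prop <- sweep(prop, 2, mu, `+`)
  # log unnormalised posterior and log proposal at both sample sets
  l1_post <- apply(dm, 1, lpost);  l1_prop <- ldprop(dm)
  l2_post <- apply(prop, 1, lpost); l2_prop <- ldprop(prop)
  ok2 <- is.finite(l2_post)
  l2_post <- l2_post[ok2]; l2_prop <- l2_prop[ok2]
  n2 <- length(l2_post)
  s1 <- n1 / (n1 + n2); s2 <- n2 / (n1 + n2)
  # l = log(q(th) / g(th))
  l1 <- l1_post - l1_prop
  l2 <- l2_post - l2_prop
  lstar <- median(l1)
  logml <- lstar # start from the posterior-sample scale
  lse <- function(v) {
    m <- max(v)
    m + log(sum(exp(v - m)))
  }
  for (it in seq_len(maxit)) {
    # numerator: mean over proposal draws of
    #   exp(l2 - lstar) / (s1 exp(l2 - lstar) + s2 exp(logml - lstar))
    a2 <- l2 - lstar
    b <- logml - lstar
    log_num_terms <- a2 - log(s1 * exp(pmin(a2, 700)) + s2 * exp(b))
    log_num <- lse(log_num_terms) - log(n2)
    a1 <- l1 - lstar
    log_den_terms <- -log(s1 * exp(pmin(a1, 700)) + s2 * exp(b))
    log_den <- lse(log_den_terms) - log(n1)
    logml_new <- lstar + log_num - log_den
    if (!is.finite(logml_new)) break
    if (abs(logml_new - logml) < tol) {
      logml <- logml_new
      break
    }
    logml <- logml_new
  }
  # crude relative SE from the variance of the numerator terms
  w <- exp(log_num_terms - max(log_num_terms))
  rse <- sd(w) / (mean(w) * sqrt(n2))
  list(log_ml = logml, rse = rse, iterations = it)
}

#' Bayes factor comparing the diversity model to the null model
#'
#' Marginal likelihoods of the full heteroscedastic model (H1: mean and
#' residual sd depend on RaoQ) and the intercept-only null (H0) are
#' estimated by bridge sampling with moment-matched normal proposals;
#' `bf > 1` favours H1. An unstable bridge estimate (relative standard error
#' above 5 percent) is flagged with a warning.
#'
#' @param fit_h1 A `hetero_bayes` fit of the full model, or a data frame, in
#'   which case both models are fitted internally.
#' @param fit_h0 A `hetero_bayes` fit with `null_model = TRUE` (ignored when
#'   `fit_h1` is a data frame).
#' @param seed Integer seed for the proposal draws (and for the internal
#'   fits when `fit_h1` is a data frame).
#' @param ... Passed to [fit_hetero_bayes()] when fitting internally.
#' @return A list of class `bayes_factor_result`: `log_bf`, `bf`,
#'   `log_ml_h1`, `log_ml_h0`, `rse_h1`, `rse_h0`.
#' @export
bayes_factor <- function(fit_h1, fit_h0 = NULL, seed = 1, ...) {
  if (is.data.frame(fit_h1)) {
    ss <- seed_stream(seed, 2)
    data <- fit_h1
    fit_h1 <- fit_hetero_bayes(data, seed = ss[1], ...)
    fit_h0 <- fit_hetero_bayes(data, seed = ss[2], null_model = TRUE, ...)
  }
  stopifnot(inherits(fit_h1, "hetero_bayes"), inherits(fit_h0, "hetero_bayes"))
  if (fit_h1$null_model || !fit_h0$null_model) {
    stop("`fit_h1` must be the full model and `fit_h0` the null model", call. = FALSE)
  }
  if (fit_h1$n != fit_h0$n) {
    stop("both models must be fitted on identical data", call. = FALSE)
  }
  b1 <- bridge_log_ml(fit_h1, seed = seed)
  b0 <- bridge_log_ml(fit_h0, seed = seed + 1)
  if (max(b1$rse, b0$rse) > 0.05) {
    warning("bridge-sampling estimate may be unstable (relative SE > 5%)")
  }
  structure(
    list(
      log_bf = b1$log_ml - b0$log_ml,
      bf = exp(b1$log_ml - b0$log_ml),
      log_ml_h1 = b1$log_ml, log_ml_h0 = b0$log_ml,
      rse_h1 = b1$rse, rse_h0 = b0$rse
    ),
    class = "bayes_factor_result"
  )
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf("<bayes_factor> log BF(H1 vs H0) = %.3f (bf = %.4g)\n", x$log_bf, x$bf))
  invisible(x)
}

#' Posterior diversity effect sizes
#'
#' The percentage reduction in mean biomass loss and in residual standard
#' deviation between a low and a high diversity value, computed draw-wise
#' from the posterior: `100 * (mu(lo) - mu(hi)) / mu(lo)` and analogously
#' for sigma.
#'
#' @param fit A full-model `hetero_bayes` fit.
#' @param raoq_lo,raoq_hi Diversity endpoints; default the observed min and
#'   max.
#' @return A tibble with one row per quantity (`mean_effect`, `sd_effect`):
#'   posterior median and 95 percent credible interval, in percent.
#' @export
effect_size_percent <- function(fit, raoq_lo = NULL, raoq_hi = NULL) {
  stopifnot(inherits(fit, "hetero_bayes"), !fit$null_model)
  raoq_lo <- raoq_lo %||% min(fit$data$raoq)
  raoq_hi <- raoq_hi %||% max(fit$data$raoq)
  if (raoq_lo >= raoq_hi) stop("`raoq_lo` must be below `raoq_hi`", call. = FALSE)
  dm <- draw_matrix(fit)
  mu_lo <- dm[, "alpha"] + dm[, "beta"] * raoq_lo
  mu_hi <- dm[, "alpha"] + dm[, "beta"] * raoq_hi
  if (median(mu_lo) <= 0) {
    stop("mean biomass loss at the low-diversity end is not positive; percentage effect undefined",
         call. = FALSE)
  }
  sig_lo <- exp(dm[, "gamma"] + dm[, "delta"] * raoq_lo)
  sig_hi <- exp(dm[, "gamma"] + dm[, "delta"] * raoq_hi)
  mean_eff <- 100 * (mu_lo - mu_hi) / mu_lo
  sd_eff <- 100 * (sig_lo - sig_hi) / sig_lo
  summarise_eff <- function(v, nm) {
    tibble::tibble(quantity = nm, estimate = median(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  }
  dplyr::bind_rows(
    summarise_eff(mean_eff, "mean_effect"),
    summarise_eff(sd_eff, "sd_effect")
  )
}
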