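#' Fit a Bayesian smoothed-trend state-space model
#'
#' Fits the second-order-difference (smoothed / local-quadratic-increment)
#' trend model
#' \deqn{y_t = \mu_t + \epsilon_t, \quad \epsilon_t \sim N(0, \sigma_\epsilon^2)}
#' \deqn{\mu_t = 2\mu_{t-1} - \mu_{t-2} + \zeta_t, \quad \zeta_t \sim N(0, \sigma_\zeta^2)}
#' to a regularly sampled series. The trend-disturbance standard deviation
#' \eqn{\sigma_\zeta} measures how strongly the trend's slope changes per
#' time step — the per-series "fluctuation" of the signal. The initial states
#' are (approximately) diffuse, so an overall level and linear trend carry no
#' information about \eqn{\sigma_\zeta}.
#'
#' Posterior sampling uses an adaptive random-walk Metropolis sampler on
#' \eqn{(\log\sigma_\zeta, \log\sigma_\epsilon)} against the Kalman-filter
#' marginal likelihood (the latent trend is integrated out), which mixes well
#' even when \eqn{\sigma_\zeta} is small; the latent trend is then drawn
#' exactly for every retained parameter draw by backward conditional
#' sampling. Priors are half-Normal on both standard deviations with scale
#' set from the series' second-difference spread (overridable).
#'
#' @param y numeric series (no missing values), e.g. a 1-Hz summary of
#'   length 120 (110 for SCR counts).
#' @param chains number of MCMC chains (default 4).
#' @param iter total iterations per chain (default 2000).
#' @param warmup warmup iterations discarded per chain (default half).
#' @param prior_scale optional length-2 numeric: half-Normal prior scales for
#'   \eqn{\sigma_\zeta} and \eqn{\sigma_\epsilon} on the scale of `y`. By
#'   default both are `max(sd(diff(y, differences = 2)), 0.001 * scale)`.
#' @param standardize center/scale the series internally for numerical
#'   stability (results are reported on the original scale). Default `TRUE`.
#' @param keep_states store posterior draws of the latent trend
#'   \eqn{\mu_{1..T}} (needed for `fitted()`, `residuals()`, `plot()`).
#' @param seed integer seed for the sampler.
#' @param series_id optional label carried into summaries.
#' @param paper_scale logical; if `TRUE` use the long sampler configuration
#'   (4 chains x 20000 iterations, 12000 warmup) instead of the desk-scale
#'   default.
#' @return an object of class `trend_fit` with components `sigma_zeta`,
#'   `sigma_eps` (iterations x chains draw matrices on the data scale), `mu`
#'   (list of per-chain draw matrices or `NULL`), `y`, `diagnostics`,
#'   `converged`, and the sampler configuration.
#' @examples
#' set.seed(1)
#' sim <- generate_trend_series(sigma_zeta = 0.05, sigma_eps = 0.02,
#'                              T = 60, seed = 1)
#' fit <- fit_trend(sim$y, iter = 600, warmup = 300, seed = 1)
#' coef(fit)
#' @export
fit_trend <- function(y, chains = 4, iter = 2000, warmup = floor(iter / 2),
                      prior_scale = NULL, standardize = TRUE,
                      keep_states = TRUE, seed = 1L, series_id = NULL,
                      paper_scale = FALSE) {
  y <- as.numeric(y)
  stop_if_not(length(y) >= 10, "series must have at least 10 time points")
  stop_if_not(!anyNA(y), "series must not contain missing values")
  if (paper_scale) { chains <- 4; iter <- 20000; warmup <- 12000 }
  stop_if_not(warmup < iter, "warmup must be smaller than iter")

  center <- if (standardize) mean(y) else 0
  scale_ <- if (standardize) max(sd(y), 1e-12) else 1
  ys <- (y - center) / scale_

  d2 <- diff(ys, differences = 2)
  s_default <- max(sd(d2), 1e-3)
  if (is.null(prior_scale)) {
    ps_z <- s_default
    ps_e <- s_default
  } else {
    stop_if_not(length(prior_scale) == 2 && all(prior_scale > 0),
                "prior_scale must be two positive numbers")
    ps_z <- prior_scale[1] / scale_
    ps_e <- prior_scale[2] / scale_
  }

  set.seed(as.integer(seed) %% 2147483646L + 1L)
  init <- cbind(log(ps_z) + runif(chains, -1.5, 0.5),
                log(max(ps_e / sqrt(6), 1e-6)) + runif(chains, -1.5, 0.5))

  res <- trend_mcmc_cpp(ys, as.integer(chains), as.integer(iter),
                        as.integer(warmup), ps_z, ps_e, init, keep_states)

  sig_zeta <- res$sigma_zeta * scale_
  sig_eps <- res$sigma_eps * scale_
  mu <- NULL
  if (keep_states) {
    mu <- lapply(res$mu, function(m) m * scale_ + center)
  }

  diag_tab <- diagnostics_table(list(sigma_zeta = sig_zeta,
                                     sigma_eps = sig_eps))
  converged <- all(diag_tab$rhat_ok, na.rm = TRUE)
  if (!converged) {
    warning("trend model did not pass the R-hat < 1.10 check; ",
            "inspect convergence_report()")
  }

  structure(list(
    series_id = series_id,
    y = y,
    sigma_zeta = sig_zeta,
    sigma_eps = sig_eps,
    mu = mu,
    accept = res$accept,
    diagnostics = diag_tab,
    converged = converged,
    config = list(chains = chains, iter = iter, warmup = warmup,
                  seed = as.integer(seed), prior_scale = c(ps_z, ps_e) * scale_,
                  standardize = standardize, center = center, scale = scale_)
  ), class = "trend_fit")
}

#' Combined posterior draws of a parameter from a trend fit
#' @param fit a `trend_fit`.
#' @param parameter `"sigma_zeta"` or `"sigma_eps"`.
#' @return numeric vector of pooled post-warmup draws.
#' @export
trend_draws <- function(fit, parameter = "sigma_zeta") {
  stopifnot(inherits(fit, "trend_fit"))
  as.vector(fit[[match.arg(parameter, c("sigma_zeta", "sigma_eps"))]])
}

#' @export
print.trend_fit <- function(x, ...) {
  sz <- post_summary(trend_draws(x, "sigma_zeta"))
  se <- post_summary(trend_draws(x, "sigma_eps"))
  cat("Smoothed-trend state-space model fit",
      if (!is.null(x$series_id)) paste0(" [", x$series_id, "]"), "\n", sep = "")
  cat(sprintf("  T = %d, %d chains x %d draws (%d warmup)\n",
              length(x$y), x$config$chains, x$config$iter, x$config$warmup))
  cat(sprintf("  sigma_zeta: EAP %.4g, 95%% CI [%.4g, %.4g]\n",
              sz$eap, sz$lower, sz$upper))
  cat(sprintf("  sigma_eps : EAP %.4g, 95%% CI [%.4g, %.4g]\n",
              se$eap, se$lower, se$upper))
  cat(sprintf("  converged: %s (max R-hat %.3f)\n",
              if (x$converged) "yes" else "NO",
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.trend_fit <- function(object, prob = 0.95, ...) {
  rows <- lapply(c("sigma_zeta", "sigma_eps"), function(p) {
    s <- post_summary(trend_draws(object, p), prob)
    d <- object$diagnostics[object$diagnostics$parameter == p, ]
    data.frame(parameter = p, eap = s$eap, lower = s$lower, upper = s$upper,
               rhat = d$rhat, ess_bulk = d$ess_bulk, ess_tail = d$ess_tail,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "prob") <- prob
  out
}

#' @export
coef.trend_fit <- function(object, ...) {
  c(sigma_zeta = mean(trend_draws(object, "sigma_zeta")),
    sigma_eps = mean(trend_draws(object, "sigma_eps")))
}

mu_matrix <- function(fit) {
  stop_if_not(!is.null(fit$mu),
              "fit was run with keep_states = FALSE; no trend draws stored")
  do.call(rbind, fit$mu)
}

#' @export
fitted.trend_fit <- function(object, ...) colMeans(mu_matrix(object))

#' @export
residuals.trend_fit <- function(object, ...) object$y - fitted(object)

#' @export
plot.trend_fit <- function(x, ...) {
  mu <- mu_matrix(x)
  est <- colMeans(mu)
  lo <- apply(mu, 2, quantile, 0.025)
  hi <- apply(mu, 2, quantile, 0.975)
  t <- seq_along(x$y)
  plot(t, x$y, type = "p", pch = 16, cex = 0.5, col = "grey40",
       xlab = "time (s)", ylab = "value",
       main = x$series_id %||% "smoothed trend", ...)
  polygon(c(t, rev(t)), c(lo, rev(hi)), border = NA,
          col = grDevices::adjustcolor("steelblue", 0.3))
  lines(t, est, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Simulate new series from the posterior of a trend fit
#'
#' Draws (\eqn{\sigma_\zeta}, \eqn{\sigma_\epsilon}) pairs from the posterior
#' and generates new series from the generative model, initialised at the
#' first two observations.
#' @param object a `trend_fit`.
#' @param nsim number of simulated series.
#' @param seed optional seed.
#' @param ... unused.
#' @return matrix `nsim x T`.
#' @export
simulate.trend_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sz <- trend_draws(object, "sigma_zeta")
  se <- trend_draws(object, "sigma_eps")
  idx <- sample.int(length(sz), nsim, replace = TRUE)
  T <- length(object$y)
  out <- matrix(NA_real_, nsim, T)
  for (i in seq_len(nsim)) {
    sim <- generate_trend_series(sz[idx[i]], se[idx[i]], T,
                                 init = object$y[1:2],
                                 seed = sample.int(2^31 - 2, 1))
    out[i, ] <- sim$y
  }
  out
}

#' Convergence report for a fitted model
#'
#' Per-parameter R-hat and bulk/tail effective sample sizes with pass/fail
#' flags against the conventional thresholds (R-hat < 1.10, ESS > 1000).
#' With a single chain, split halves are compared (split R-hat).
#'
#' @param fit a `trend_fit` or `contrast_fit`.
#' @param rhat_limit,ess_limit thresholds; defaults 1.10 and 1000.
#' @return data.frame as [diagnostics_table()].
#' @export
convergence_report <- function(fit, rhat_limit = 1.10, ess_limit = 1000) {
  if (inherits(fit, "trend_fit")) {
    return(diagnostics_table(list(sigma_zeta = fit$sigma_zeta,
                                  sigma_eps = fit$sigma_eps),
                             rhat_limit, ess_limit))
  }
  if (inherits(fit, "contrast_fit")) {
    return(diagnostics_table(fit$draws, rhat_limit, ess_limit))
  }
  stop("convergence_report() expects a trend_fit or contrast_fit")
}

#' Average the fluctuation parameter across a condition's videos
#'
#' Draw-wise mean of the \eqn{\sigma_\zeta} posterior across the (independent)
#' fits of one condition's videos, draws paired by index.
#'
#' @param fits list of `trend_fit` objects (typically the condition's two
#'   videos).
#' @return numeric vector of averaged draws, with attribute `"flagged"` if
#'   any contributing fit failed its convergence check.
#' @export
average_condition_sigma <- function(fits) {
  stop_if_not(length(fits) >= 1, "need at least one fit")
  draws <- lapply(fits, trend_draws, parameter = "sigma_zeta")
  n <- vapply(draws, length, integer(1))
  stop_if_not(length(unique(n)) == 1L,
              "fits have different post-warmup draw counts; cannot pair draws")
  flagged <- !all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  if (flagged) warning("averaging includes a fit flagged as non-converged")
  out <- Reduce(`+`, draws) / length(draws)
  attr(out, "flagged") <- flagged
  out
}

#' Condition contrasts of trend fluctuation
#'
#' Computes the posterior of the difference between one condition's averaged
#' \eqn{\sigma_\zeta} and the mean of the other two conditions'
#' (\eqn{\sigma_{dif}}), for the awe and amusement conditions.
#'
#' @param condition_draws named list with elements `neutral`, `amusement`,
#'   `awe`: equal-length draw vectors of per-condition averaged
#'   \eqn{\sigma_\zeta} (see [average_condition_sigma()]).
#' @param prob credible level (default 0.95).
#' @return object of class `fluct_contrast`: per-contrast EAP, CI bounds,
#'   significance flag (CI excludes 0), and the draw vectors.
#' @export
fluctuation_contrast <- function(condition_draws, prob = 0.95) {
  need <- c("neutral", "amusement", "awe")
  stop_if_not(all(need %in% names(condition_draws)),
              "condition_draws must contain neutral, amusement and awe")
  cd <- condition_draws[need]
  n <- vapply(cd, length, integer(1))
  stop_if_not(length(unique(n)) == 1L, "draw vectors must have equal length")
  dif <- list(
    awe_vs_others = cd$awe - (cd$amusement + cd$neutral) / 2,
    amusement_vs_others = cd$amusement - (cd$awe + cd$neutral) / 2
  )
  tab <- do.call(rbind, lapply(names(dif), function(nm) {
    s <- post_summary(dif[[nm]], prob)
    data.frame(contrast = nm, eap = s$eap, lower = s$lower, upper = s$upper,
               significant = s$significant, stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, draws = dif,
                 condition_eap = vapply(cd, mean, numeric(1)),
                 prob = prob),
            class = "fluct_contrast")
}

#' @export
print.fluct_contrast <- function(x, ...) {
  cat("Fluctuation (sigma_zeta) condition contrasts\n")
  cat(sprintf("  condition EAPs: neutral %.4g, amusement %.4g, awe %.4g\n",
              x$condition_eap["neutral"], x$condition_eap["amusement"],
              x$condition_eap["awe"]))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  sigma_dif(%s): %.4g, %d%% CI [%.4g, %.4g]%s\n",
                r$contrast, r$eap, round(100 * x$prob), r$lower, r$upper,
                if (r$significant) " *" else ""))
  }
  invisible(x)
}
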