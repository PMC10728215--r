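# desk-scale sampler settings used throughout: 4 chains x 2000 (1000 warmup)

test_that("fit contract: draws, diagnostics, methods", {
  sim <- generate_trend_series(0.05, 0.02, 120, seed = 11)
  fit <- quiet_fit_trend(sim$y, seed = 2, series_id = "sim")
  expect_s3_class(fit, "trend_fit")
  expect_equal(dim(fit$sigma_zeta), c(1000, 4))
  expect_true(all(fit$sigma_zeta > 0) && all(fit$sigma_eps > 0))

  s <- summary(fit)
  expect_equal(s$parameter, c("sigma_zeta", "sigma_eps"))
  expect_true(all(s$lower <= s$eap & s$eap <= s$upper))
  expect_true(all(is.finite(s$rhat)))

  expect_named(coef(fit), c("sigma_zeta", "sigma_eps"))
  expect_length(fitted(fit), 120)
  expect_equal(residuals(fit), sim$y - fitted(fit))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(3, 120))
  expect_output(print(fit), "sigma_zeta")

  # smoothed trend tracks the latent truth
  expect_lt(sqrt(mean((fitted(fit) - sim$mu)^2)), 2 * 0.02)

  expect_error(fit_trend(rep(1, 5)), "at least 10")
  expect_error(fit_trend(c(rnorm(50), NA)), "missing")
})

test_that("sampler recovers sigma_zeta and matches an independent engine", {
  sim <- generate_trend_series(0.05, 0.02, 80, seed = 21)
  fit <- quiet_fit_trend(sim$y, seed = 5, keep_states = FALSE)
  ci <- quantile(trend_draws(fit), c(0.025, 0.975))
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])

  # independent oracle: the same model in JAGS (single-site Gibbs engine)
  library(rjags)
  sc <- max(sd(diff(sim$y, differences = 2)), 1e-3)
  jm <- rjags::jags.model(textConnection("
    model {
      for (t in 3:T) { mu[t] ~ dnorm(2 * mu[t-1] - mu[t-2], pz) }
      for (t in 1:T) { y[t] ~ dnorm(mu[t], pe) }
      mu[1] ~ dnorm(y1, 1e-6)
      mu[2] ~ dnorm(y1, 1e-6)
      sz ~ dnorm(0, 1 / (s * s)) T(0,)
      se ~ dnorm(0, 1 / (s * s)) T(0,)
      pz <- 1 / (sz * sz)
      pe <- 1 / (se * se)
    }"),
    data = list(y = sim$y, T = length(sim$y), s = sc, y1 = sim$y[1]),
    n.chains = 3, n.adapt = 2000, quiet = TRUE)
  update(jm, 10000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("sz", "se"), 20000, thin = 5,
                            progress.bar = "none")
  d <- do.call(rbind, sm)
  expect_equal(mean(trend_draws(fit, "sigma_zeta")), mean(d[, "sz"]),
               tolerance = 0.20)
  expect_equal(mean(trend_draws(fit, "sigma_eps")), mean(d[, "se"]),
               tolerance = 0.35)
})

test_that("noiseless quadratic has near-zero fluctuation on unit scale", {
  yq <- 0.01 * (1:120)^2
  yqs <- (yq - mean(yq)) / sd(yq)
  fit <- quiet_fit_trend(yqs, seed = 3, keep_states = FALSE)
  expect_lt(quantile(trend_draws(fit), 0.975), 0.01)
})

test_that("sigma_zeta is invariant to level and linear trend", {
  sim <- generate_trend_series(0.03, 0.02, 120, seed = 31)
  f0 <- quiet_fit_trend(sim$y, seed = 7, keep_states = FALSE)
  shifted <- sim$y + 5 + 0.3 * seq_along(sim$y)
  f1 <- quiet_fit_trend(shifted, seed = 8, keep_states = FALSE)
  d0 <- trend_draws(f0); d1 <- trend_draws(f1)
  mcse <- sd(d0) / sqrt(ess_bulk(f0$sigma_zeta)) +
    sd(d1) / sqrt(ess_bulk(f1$sigma_zeta))
  expect_lt(abs(mean(d0) - mean(d1)), max(4 * mcse, 0.02 * mean(d0)))
})

test_that("sigma posteriors scale with the series", {
  sim <- generate_trend_series(0.05, 0.02, 120, seed = 41)
  f1 <- quiet_fit_trend(sim$y, seed = 9, keep_states = FALSE)
  f10 <- quiet_fit_trend(10 * sim$y, seed = 9, keep_states = FALSE)
  expect_equal(mean(trend_draws(f10)) / mean(trend_draws(f1)), 10,
               tolerance = 0.05)
  expect_equal(mean(trend_draws(f10, "sigma_eps")) /
                 mean(trend_draws(f1, "sigma_eps")), 10, tolerance = 0.05)
})

test_that("condition averaging pairs draws by index", {
  sim <- generate_trend_series(0.05, 0.02, 30, seed = 51)
  f <- quiet_fit_trend(sim$y, chains = 2, iter = 200, warmup = 100,
                       seed = 1, keep_states = FALSE)
  # identical fits average to themselves
  avg <- suppressWarnings(average_condition_sigma(list(f, f)))
  expect_equal(as.numeric(avg), trend_draws(f))

  # index-paired arithmetic on constructed draws
  fa <- f; fb <- f
  fa$sigma_zeta <- matrix(c(0.1, 0.3), 2, 1)
  fb$sigma_zeta <- matrix(c(0.2, 0.4), 2, 1)
  expect_equal(as.numeric(suppressWarnings(
    average_condition_sigma(list(fa, fb)))), c(0.15, 0.35))

  # mismatched draw counts are rejected; flagged fits propagate a warning
  fc <- f; fc$sigma_zeta <- matrix(0.1, 3, 1)
  expect_error(average_condition_sigma(list(fa, fc)), "draw counts")
  fd <- fa; fd$converged <- FALSE
  expect_warning(avg2 <- average_condition_sigma(list(fd, fb)),
                 "non-converged")
  expect_true(attr(avg2, "flagged"))
})

test_that("fluctuation contrasts: identities, arithmetic, significance", {
  same <- list(neutral = rep(0.02, 100), amusement = rep(0.02, 100),
               awe = rep(0.02, 100))
  fc0 <- fluctuation_contrast(same)
  expect_equal(fc0$table$eap, c(0, 0))
  expect_false(any(fc0$table$significant))

  built <- list(neutral = rep(0.02, 100), amusement = rep(0.02, 100),
                awe = rep(0.05, 100))
  fc1 <- fluctuation_contrast(built)
  awe_row <- fc1$table[fc1$table$contrast == "awe_vs_others", ]
  expect_equal(awe_row$eap, 0.03)

  expect_error(fluctuation_contrast(built[1:2]), "awe")
  expect_output(print(fc1), "sigma_dif")
})

test_that("posterior ordering detects a 3x fluctuation difference", {
  p_pos <- replicate(3, {
    seeds <- sample.int(1e6, 2)
    a <- generate_trend_series(0.06, 0.02, 120, seed = seeds[1])
    b <- generate_trend_series(0.02, 0.02, 120, seed = seeds[2])
    fa <- quiet_fit_trend(a$y, seed = seeds[1], keep_states = FALSE)
    fb <- quiet_fit_trend(b$y, seed = seeds[2], keep_states = FALSE)
    mean(trend_draws(fa) - trend_draws(fb) > 0)
  })
  expect_gt(median(p_pos), 0.95)
})

test_that("convergence report flags thresholds and handles one chain", {
  sim <- generate_trend_series(0.05, 0.02, 60, seed = 61)
  fit <- quiet_fit_trend(sim$y, seed = 3, keep_states = FALSE)
  rep_ <- convergence_report(fit)
  expect_setequal(rep_$parameter, c("sigma_zeta", "sigma_eps"))
  expect_true(all(c("rhat", "ess_bulk", "ess_tail", "rhat_ok", "ess_ok")
                  %in% names(rep_)))

  # custom thresholds are honoured
  strict <- convergence_report(fit, rhat_limit = 1.0000001)
  expect_false(all(strict$rhat_ok))

  # single chain: split R-hat is still defined
  f1 <- quiet_fit_trend(sim$y, chains = 1, iter = 1000, warmup = 500,
                        seed = 4, keep_states = FALSE)
  expect_true(is.finite(convergence_report(f1)$rhat[1]))
})
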