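test_that("SCR kernel has unit maximum at its analytic peak time", {
  tpk <- scr_kernel_peak_time(0.75, 2.5)
  expect_equal(scr_kernel(tpk, 0.75, 2.5), 1, tolerance = 1e-12)
  tt <- seq(0, 30, by = 0.001)
  expect_lt(max(scr_kernel(tt, 0.75, 2.5)), 1 + 1e-9)
  expect_equal(tt[which.max(scr_kernel(tt, 0.75, 2.5))], tpk,
               tolerance = 1e-3)
  # half-decay solves K = 1/2 beyond the peak
  th <- scr_kernel_half_decay_time(0.75, 2.5)
  expect_gt(th, tpk)
  expect_equal(scr_kernel(th, 0.75, 2.5), 0.5, tolerance = 1e-8)
})

test_that("EDA generator: identity case, kernel superposition, determinism", {
  # no events, no noise, flat tonic -> constant trace
  flat <- generate_eda_trace(tonic_params = list(level = 2, drift = 0,
                                                 rw_sd = 0),
                             noise_sd = 0, duration = 10, seed = 1)
  expect_equal(unique(flat$values), 2)
  expect_length(flat$values, 2500)

  # single event: max above tonic equals amplitude at the analytic peak
  ev <- data.frame(time = 30, amplitude = 0.5)
  tr <- generate_eda_trace(ev, tonic_params = list(level = 2, drift = 0,
                                                   rw_sd = 0),
                           noise_sd = 0, seed = 1)
  expect_equal(max(tr$values) - 2, 0.5, tolerance = 1e-4)
  tpk <- scr_kernel_peak_time(0.75, 2.5)
  t_at_max <- (which.max(tr$values) - 1) / tr$rate
  expect_equal(t_at_max, 30 + tpk, tolerance = 1 / tr$rate)

  # determinism
  a <- generate_eda_trace(ev, seed = 7)
  b <- generate_eda_trace(ev, seed = 7)
  expect_identical(a$values, b$values)

  # rejections
  expect_error(generate_eda_trace(data.frame(time = 200, amplitude = 1),
                                  duration = 120), "within")
  expect_error(generate_eda_trace(ev, kernel_params = list(tau_rise = 3,
                                                           tau_decay = 2)),
               "tau_rise")
})

test_that("pupil generator: degenerate flat case, blinks, rejections", {
  p0 <- generate_pupil_trace(3.5, sigma_zeta = 0, noise_sd = 0,
                             blink_rate = 0, duration = 20, seed = 1)
  expect_equal(unique(p0$values), 3.5)
  expect_false(any(p0$blink_mask))

  pb <- generate_pupil_trace(3.5, 0.02, 0.01, blink_rate = 20,
                             duration = 60, seed = 2)
  expect_gt(mean(is.na(pb$values)), 0)
  expect_identical(is.na(pb$values), pb$blink_mask)

  expect_error(generate_pupil_trace(3.5, sigma_zeta = -1), "non-negative")
})

test_that("joystick generator matches the reported awe plateau and bounds", {
  z <- generate_joystick_trace("neutral", plateau = 0, jitter_sd = 0,
                               duration = 30, seed = 1)
  expect_true(all(z$values == 0))

  awe <- generate_joystick_trace("awe", plateau = 0.19, jitter_sd = 0.01,
                                 duration = 120, seed = 3)
  tt <- (seq_along(awe$values) - 1) / awe$rate
  expect_equal(mean(awe$values[tt >= 20]), 0.19, tolerance = 0.01)
  # rises within ~10 s then stays up
  expect_lt(mean(awe$values[tt < 2]), 0.05)

  clip <- generate_joystick_trace("awe", plateau = 0.5, jitter_sd = 0.05,
                                  duration = 30, seed = 4)
  expect_true(all(clip$values <= 0.5 & clip$values >= 0))
  expect_error(generate_joystick_trace("awe", plateau = 0.7), "\\[0, 0.5\\]")
})

test_that("trend-series generator: noiseless recursion and variance identity", {
  line <- generate_trend_series(0, 0, 10, init = c(0, 1), seed = 1)
  expect_equal(line$y, 0:9)
  expect_equal(line$mu, line$y)

  # Var(second difference of y) = sigma_zeta^2 + 6 sigma_eps^2
  s <- generate_trend_series(0.05, 0.02, 10000, seed = 3)
  v <- var(diff(s$y, differences = 2))
  expect_equal(v, 0.05^2 + 6 * 0.02^2, tolerance = 0.1)

  a <- generate_trend_series(0.03, 0.01, 50, seed = 9)
  b <- generate_trend_series(0.03, 0.01, 50, seed = 9)
  expect_identical(a$y, b$y)

  expect_error(generate_trend_series(-0.1, 0, 10), "non-negative")
  expect_error(generate_trend_series(0.1, 0, 2), "at least 3")
})

test_that("session generator produces complete labelled tables", {
  cfg <- tiny_session_config(seed = 5)
  s <- generate_session(cfg)
  expect_equal(nrow(s$trials), 4 * 6)
  expect_setequal(unique(s$trials$condition),
                  c("neutral", "amusement", "awe"))
  expect_true(all(s$trials$awe >= 1 & s$trials$awe <= 7))
  rating_cols <- rownames(cfg$rating_means)
  expect_true(all(rating_cols %in% names(s$trials)))
  expect_length(s$traces, 4)
  expect_named(s$traces[[1]], cfg$videos$video_id)
  # every participant saw each condition's two videos in some order
  expect_true(all(tapply(s$trials$order_within,
                         paste(s$trials$participant, s$trials$condition),
                         function(o) all(sort(o) == 1:2))))
})

test_that("ground truth round-trips every injected SCR event exactly", {
  s <- generate_session(tiny_session_config(seed = 11))
  gt <- s$ground_truth$events
  for (i in seq_len(min(nrow(gt), 50))) {
    tr <- s$traces[[gt$participant[i]]][[gt$video[i]]]$eda
    expect_true(any(abs(tr$events$time - gt$onset[i]) < 1e-12 &
                      abs(tr$events$amplitude - gt$amplitude[i]) < 1e-12))
  }
  expect_true(all(gt$onset >= 0 & gt$onset <= 30))
  expect_true(all(gt$amplitude > 0))
})

test_that("sessions are deterministic given config and seed", {
  a <- generate_session(tiny_session_config(seed = 21, n = 2))
  b <- generate_session(tiny_session_config(seed = 21, n = 2))
  expect_identical(a$trials, b$trials)
  expect_identical(a$traces[[1]][[1]]$eda$values,
                   b$traces[[1]][[1]]$eda$values)
  expect_identical(a$traces[[2]][[3]]$pupil$values,
                   b$traces[[2]][[3]]$pupil$values)
  c <- generate_session(tiny_session_config(seed = 22, n = 2))
  expect_false(identical(a$traces[[1]][[1]]$eda$values,
                         c$traces[[1]][[1]]$eda$values))
})

test_that("zero-effect config yields exchangeable conditions downstream", {
  cfg <- synthetic_config(
    n_participants = 12, duration_s = 20, seed = 31,
    rating_means = matrix(3, 1, 3,
                          dimnames = list("awe",
                                          c("neutral", "amusement", "awe"))))
  s <- generate_session(cfg)
  d <- build_design(s$trials, "awe", covariates = character(0))
  fit <- fit_hier(d, chains = 2, iter = 800, warmup = 400, seed = 1)
  tab <- fit$table
  expect_false(tab$significant[tab$term == "awe_contrast"])
  expect_false(tab$significant[tab$term == "amusement_contrast"])
})
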