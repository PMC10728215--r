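#' Canonical phasic SCR kernel
#'
#' Bi-exponential skin conductance response shape
#' \deqn{K(t) = c\,(e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}), \quad t \ge 0,}
#' normalized so that \eqn{\max_t K(t) = 1}. Zero for `t < 0`.
#'
#' @param t time in seconds relative to event onset.
#' @param tau_rise,tau_decay time constants in seconds; must satisfy
#'   `tau_rise < tau_decay`.
#' @return kernel values, same length as `t`.
#' @export
scr_kernel <- function(t, tau_rise = 0.75, tau_decay = 2.5) {
  stop_if_not(tau_rise > 0 && tau_decay > tau_rise,
              "need 0 < tau_rise < tau_decay")
  tpk <- scr_kernel_peak_time(tau_rise, tau_decay)
  peak <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- ifelse(t >= 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak, 0)
  out
}

#' @rdname scr_kernel
#' @return `scr_kernel_peak_time()`: the analytic time of the kernel maximum,
#'   \eqn{(\ln\tau_{decay} - \ln\tau_{rise}) / (1/\tau_{rise} - 1/\tau_{decay})}.
#' @export
scr_kernel_peak_time <- function(tau_rise = 0.75, tau_decay = 2.5) {
  (log(tau_decay) - log(tau_rise)) / (1 / tau_rise - 1 / tau_decay)
}

#' @rdname scr_kernel
#' @return `scr_kernel_half_decay_time()`: the first time after the peak at
#'   which the kernel falls to one half (solved numerically).
#' @export
scr_kernel_half_decay_time <- function(tau_rise = 0.75, tau_decay = 2.5) {
  tpk <- scr_kernel_peak_time(tau_rise, tau_decay)
  f <- function(t) scr_kernel(t, tau_rise, tau_decay) - 0.5
  stats::uniroot(f, c(tpk, tpk + 20 * tau_decay), tol = 1e-10)$root
}

new_trace <- function(type, values, rate, participant = NA, video = NA,
                      condition = NA, extra = list()) {
  structure(c(list(participant = participant, video = video,
                   condition = condition, rate = rate, values = values),
              extra),
            class = c(paste0(type, "_trace"), "awedyn_trace"))
}

#' @export
print.awedyn_trace <- function(x, ...) {
  cat(sprintf("<%s> participant=%s video=%s condition=%s: %d samples @ %g Hz (%.1f s)\n",
              class(x)[1], x$participant, x$video, x$condition,
              length(x$values), x$rate, length(x$values) / x$rate))
  invisible(x)
}

#' Generate a raw electrodermal (EDA) trace
#'
#' Tonic drift (linear trend plus slow random walk) with phasic SCR events
#' superimposed as bi-exponential kernels, plus Gaussian measurement noise.
#'
#' @param events data.frame with columns `time` (s, within the recording) and
#'   `amplitude` (microsiemens, > 0); zero rows allowed.
#' @param kernel_params list with `tau_rise`, `tau_decay` (s).
#' @param tonic_params list with `level` (microsiemens), `drift`
#'   (microsiemens/s) and `rw_sd` (random-walk SD per sqrt(second)).
#' @param noise_sd Gaussian measurement noise SD (microsiemens).
#' @param rate sampling rate in Hz (study hardware: 250).
#' @param duration recording length in seconds.
#' @param seed integer seed.
#' @return an `eda_trace` object (`values` in microsiemens).
#' @export
generate_eda_trace <- function(events = data.frame(time = numeric(),
                                                   amplitude = numeric()),
                               kernel_params = list(tau_rise = 0.75,
                                                    tau_decay = 2.5),
                               tonic_params = list(level = 2, drift = 0.001,
                                                   rw_sd = 0.003),
                               noise_sd = 0.01, rate = 250, duration = 120,
                               seed = 1L) {
  stop_if_not(rate > 0 && duration > 0, "rate and duration must be positive")
  stop_if_not(all(events$time >= 0 & events$time <= duration),
              "event times must lie within [0, duration]")
  stop_if_not(all(events$amplitude > 0), "event amplitudes must be positive")
  stop_if_not(kernel_params$tau_rise < kernel_params$tau_decay,
              "tau_rise must be smaller than tau_decay")
  set.seed(as.integer(seed))
  n <- round(rate * duration)
  tt <- (seq_len(n) - 1) / rate
  tonic <- tonic_params$level + tonic_params$drift * tt
  if (tonic_params$rw_sd > 0) {
    tonic <- tonic + cumsum(rnorm(n, 0, tonic_params$rw_sd / sqrt(rate)))
  }
  phasic <- numeric(n)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      phasic <- phasic + events$amplitude[i] *
        scr_kernel(tt - events$time[i],
                   kernel_params$tau_rise, kernel_params$tau_decay)
    }
  }
  vals <- tonic + phasic + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  new_trace("eda", vals, rate,
            extra = list(events = events, kernel_params = kernel_params))
}

#' Generate a raw pupil-diameter trace
#'
#' The latent pupil trend evolves at 1 Hz with a stochastically perturbed,
#' damped slope: \eqn{\mu_t = \mu_{t-1} + \phi(\mu_{t-1} - \mu_{t-2}) +
#' \zeta_t} with \eqn{\zeta_t \sim N(0, \sigma_\zeta^2)}. With `damping`
#' \eqn{\phi = 1} this is exactly the second-order random walk of the
#' fitted trend model; the default \eqn{\phi = 0.7} keeps the simulated
#' diameter physiologically bounded over minutes (an undamped integrated
#' random walk wanders by many millimetres) while `sigma_zeta` still sets
#' the trend-fluctuation magnitude. The trend is linearly upsampled to the
#' camera frame rate, observed with Gaussian noise, and interrupted by
#' blink dropouts (missing samples of 100-400 ms).
#'
#' @param baseline starting diameter (mm, > 0).
#' @param sigma_zeta trend-disturbance SD at 1 Hz (mm); >= 0.
#' @param noise_sd measurement noise SD (mm).
#' @param blink_rate blinks per minute.
#' @param rate sampling rate in Hz (study camera: 120).
#' @param duration seconds.
#' @param damping slope persistence \eqn{\phi \in [0, 1]}.
#' @param seed integer seed.
#' @return a `pupil_trace` with `values` (mm; `NA` during blinks),
#'   `blink_mask`, and the latent 1-Hz trend in `latent`.
#' @export
generate_pupil_trace <- function(baseline = 3.5, sigma_zeta = 0.02,
                                 noise_sd = 0.02, blink_rate = 6,
                                 rate = 120, duration = 120, damping = 0.7,
                                 seed = 1L) {
  stop_if_not(baseline > 0, "baseline must be positive")
  stop_if_not(sigma_zeta >= 0, "sigma_zeta must be non-negative")
  stop_if_not(damping >= 0 && damping <= 1, "damping must lie in [0, 1]")
  set.seed(as.integer(seed))
  T1 <- max(ceiling(duration), 3)
  latent <- numeric(T1)
  latent[1:2] <- baseline
  zeta <- rnorm(T1 - 2, 0, sigma_zeta)
  for (t in 3:T1) {
    latent[t] <- latent[t - 1] + damping * (latent[t - 1] - latent[t - 2]) +
      zeta[t - 2]
  }
  n <- round(rate * duration)
  tt <- (seq_len(n) - 1) / rate
  vals <- approx(x = seq_len(T1) - 1, y = latent, xout = tt, rule = 2)$y
  if (noise_sd > 0) vals <- vals + rnorm(n, 0, noise_sd)
  mask <- rep(FALSE, n)
  n_blinks <- rpois(1, blink_rate * duration / 60)
  if (n_blinks > 0) {
    starts <- runif(n_blinks, 0, duration)
    durs <- runif(n_blinks, 0.1, 0.4)
    for (b in seq_len(n_blinks)) {
      idx <- which(tt >= starts[b] & tt < starts[b] + durs[b])
      mask[idx] <- TRUE
    }
  }
  vals[mask] <- NA_real_
  new_trace("pupil", vals, rate,
            extra = list(blink_mask = mask, latent = latent,
                         sigma_zeta = sigma_zeta))
}

#' Generate a joystick (supernatural-presence) trace
#'
#' In the awe condition the inclination rises sigmoidally, reaching its
#' plateau by about `rise_time_s` seconds, and then stays constant; in the
#' other conditions it stays near a low constant level. Jitter is added and
#' the trace is clipped to the physical range `[0, 0.5]`.
#'
#' @param condition `"neutral"`, `"amusement"` or `"awe"`.
#' @param plateau plateau level in `[0, 0.5]`.
#' @param rise_time_s time to reach the plateau (awe only; default 10 s).
#' @param jitter_sd Gaussian jitter SD.
#' @param rate sampling rate in Hz.
#' @param duration seconds.
#' @param seed integer seed.
#' @return a `joystick_trace` (`values` in `[0, 0.5]`).
#' @export
generate_joystick_trace <- function(condition = "awe", plateau = 0.19,
                                    rise_time_s = 10, jitter_sd = 0.01,
                                    rate = 60, duration = 120, seed = 1L) {
  stop_if_not(plateau >= 0 && plateau <= 0.5, "plateau must lie in [0, 0.5]")
  set.seed(as.integer(seed))
  n <- round(rate * duration)
  tt <- (seq_len(n) - 1) / rate
  if (identical(condition, "awe")) {
    level <- plateau / (1 + exp(-(tt - rise_time_s / 2) * 10 / rise_time_s))
  } else {
    level <- rep(plateau, n)
  }
  vals <- level + if (jitter_sd > 0) rnorm(n, 0, jitter_sd) else 0
  vals <- pmin(pmax(vals, 0), 0.5)
  new_trace("joystick", vals, rate, condition = condition,
            extra = list(plateau = plateau))
}

#' Simulate a series from the smoothed-trend model
#'
#' Generative twin of the model fitted by [fit_trend()]:
#' \eqn{y_t = \mu_t + \epsilon_t}, \eqn{\mu_t = 2\mu_{t-1} - \mu_{t-2} +
#' \zeta_t} with independent Gaussian disturbances.
#'
#' @param sigma_zeta trend-disturbance SD (>= 0).
#' @param sigma_eps observation-noise SD (>= 0).
#' @param T series length (>= 3).
#' @param init numeric length 2: \eqn{(\mu_1, \mu_2)}.
#' @param seed integer seed.
#' @return list with `y` (observed series), `mu` (latent trend) and the true
#'   parameters.
#' @export
generate_trend_series <- function(sigma_zeta, sigma_eps, T,
                                  init = c(0, 0), seed = 1L) {
  stop_if_not(sigma_zeta >= 0 && sigma_eps >= 0, "SDs must be non-negative")
  stop_if_not(T >= 3, "T must be at least 3")
  set.seed(as.integer(seed))
  mu <- numeric(T)
  mu[1:2] <- init
  zeta <- rnorm(T - 2, 0, sigma_zeta)
  for (t in 3:T) mu[t] <- 2 * mu[t - 1] - mu[t - 2] + zeta[t - 2]
  y <- mu + if (sigma_eps > 0) rnorm(T, 0, sigma_eps) else 0
  list(y = y, mu = mu, sigma_zeta = sigma_zeta, sigma_eps = sigma_eps)
}

#' Configuration for a synthetic experiment session
#'
#' Defaults emulate the study conditions: 77 participants, six 2-min videos
#' (two per condition), EDA at 250 Hz, pupil at 120 Hz; SCR event rates,
#' pupil baselines and fluctuation, joystick plateaus, and rating means are
#' calibrated to the reported condition means. Any field can be overridden.
#'
#' @param ... overrides of the default fields (see the returned list).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_participants = 77,
    videos = data.frame(
      video_id = c("neutral-1", "neutral-2", "amusement-1", "amusement-2",
                   "awe-1", "awe-2"),
      condition = rep(c("neutral", "amusement", "awe"), each = 2),
      stringsAsFactors = FALSE),
    duration_s = 120,
    eda_rate = 250,
    pupil_rate = 120,
    joystick_rate = 60,
    # events/min chosen so the expected retained count over the 110-s
    # analysis window matches the reported per-video means
    # (0.91 / 1.68 / 2.38 for neutral / amusement / awe)
    scr_event_rate = c(neutral = 0.50, amusement = 0.92, awe = 1.30),
    # rate surges while the camera view opens up in the awe videos
    awe_burst_windows = list("awe-1" = c(90, 110), "awe-2" = c(10, 30)),
    awe_burst_factor = 3,
    scr_amplitude_meanlog = c(neutral = -0.79, amusement = -0.70,
                              awe = -0.61),
    scr_amplitude_sdlog = 0.4,
    kernel_params = list(tau_rise = 0.75, tau_decay = 2.5),
    tonic_params = list(level = 2, drift = 0.001, rw_sd = 0.003),
    eda_noise_sd = 0.01,
    pupil_baseline = c(neutral = 3.41, amusement = 3.93, awe = 3.54),
    pupil_sigma_zeta = c(neutral = 0.015, amusement = 0.02, awe = 0.07),
    pupil_noise_sd = 0.01,
    blink_rate = 6,
    joystick_plateau = c(neutral = 0.03, amusement = 0.04, awe = 0.19),
    joystick_jitter_sd = 0.01,
    joystick_rise_time_s = 10,
    rating_means = rbind(
      awe = c(neutral = 1.52, amusement = 2.16, awe = 4.69),
      amusement = c(neutral = 3.19, amusement = 4.72, awe = 3.47),
      small_self = c(neutral = 4.10, amusement = 3.57, awe = 2.17),
      self_boundary = c(neutral = 4.41, amusement = 3.43, awe = 2.80),
      agency = c(neutral = 1.32, amusement = 1.56, awe = 2.70),
      non_agency = c(neutral = 2.41, amusement = 2.14, awe = 5.25),
      fear = c(neutral = 1.40, amusement = 1.30, awe = 2.20)),
    rating_sd = 1.0,
    random_intercept_sd = 0.5,
    temperature_mean = 24, temperature_sd = 1.5,
    humidity_mean = 50, humidity_sd = 8,
    age_mean = 21.44, age_sd = 3.11,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  stop_if_not(length(unknown) == 0,
              paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg <- modifyList(cfg, over)
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  stop_if_not(cfg$duration_s > 0, "duration_s must be positive")
  stop_if_not(all(c(cfg$eda_rate, cfg$pupil_rate, cfg$joystick_rate) > 0),
              "sampling rates must be positive")
  stop_if_not(all(cfg$scr_event_rate >= 0), "event rates must be >= 0")
  stop_if_not(all(cfg$joystick_plateau >= 0 & cfg$joystick_plateau <= 0.5),
              "joystick plateaus must lie in [0, 0.5]")
  stop_if_not(cfg$random_intercept_sd >= 0 && cfg$rating_sd >= 0 &&
                cfg$pupil_noise_sd >= 0 && all(cfg$pupil_sigma_zeta >= 0),
              "SDs must be non-negative")
  stop_if_not(all(cfg$videos$condition %in%
                    c("neutral", "amusement", "awe")),
              "video conditions must be neutral/amusement/awe")
  invisible(cfg)
}

rtruncnorm17 <- function(n, mean, sd, lo = 1, hi = 7) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

# thinned inhomogeneous Poisson event times for one video
draw_scr_events <- function(cfg, video_id, condition, seed) {
  set.seed(seed)
  base <- cfg$scr_event_rate[[condition]]
  burst <- cfg$awe_burst_windows[[video_id]]
  f <- cfg$awe_burst_factor
  D <- cfg$duration_s
  if (is.null(burst) || base == 0) {
    lambda <- function(t) rep(base, length(t))
    rmax <- base
  } else {
    w <- diff(burst)
    # scale the baseline so the expected total stays at base * D
    b0 <- base * D / ((D - w) + f * w)
    lambda <- function(t) ifelse(t >= burst[1] & t < burst[2], f * b0, b0)
    rmax <- f * b0
  }
  n_cand <- rpois(1, rmax * D / 60)
  tcand <- sort(runif(n_cand, 0, D))
  keep <- runif(n_cand) < lambda(tcand) / rmax
  times <- tcand[keep]
  amps <- stats::rlnorm(length(times),
                        cfg$scr_amplitude_meanlog[[condition]],
                        cfg$scr_amplitude_sdlog)
  data.frame(time = times, amplitude = amps)
}

#' Generate a complete synthetic experiment session
#'
#' Produces raw EDA, pupil and joystick traces for every participant x video,
#' post-video ratings with participant random intercepts, session covariates,
#' and a ground-truth record of everything injected (SCR event times and
#' amplitudes, per-condition pupil fluctuation, joystick plateaus, rating
#' means, random intercepts).
#'
#' @param config a [synthetic_config()].
#' @return list with `traces` (nested list: `traces[[participant]][[video]]`
#'   holding `eda`, `pupil`, `joystick` trace objects), `trials` (one row per
#'   participant x video: ratings, order, covariates), and `ground_truth`.
#' @export
generate_session <- function(config = synthetic_config()) {
  cfg <- validate_config(config)
  set.seed(as.integer(cfg$seed))
  np <- cfg$n_participants
  vids <- cfg$videos
  conds <- vids$condition

  participants <- sprintf("p%02d", seq_len(np))
  intercepts <- rnorm(np, 0, cfg$random_intercept_sd)
  temperature <- rnorm(np, cfg$temperature_mean, cfg$temperature_sd)
  humidity <- rnorm(np, cfg$humidity_mean, cfg$humidity_sd)
  age <- round(pmax(rnorm(np, cfg$age_mean, cfg$age_sd), 18))
  gender <- sample(rep(c("f", "m"), length.out = np))

  traces <- vector("list", np)
  names(traces) <- participants
  trial_rows <- list()
  gt_events <- list()

  for (p in seq_len(np)) {
    ord <- sample(nrow(vids))  # presentation position of the six videos
    # order within condition: rank of presentation position among the
    # condition's two videos
    pos <- ord
    owc <- integer(nrow(vids))
    for (cc in unique(conds)) {
      sel <- which(conds == cc)
      owc[sel] <- rank(pos[sel])
    }
    traces[[p]] <- vector("list", nrow(vids))
    names(traces[[p]]) <- vids$video_id
    for (v in seq_len(nrow(vids))) {
      vid <- vids$video_id[v]; cond <- conds[v]
      base_idx <- (p - 1) * nrow(vids) + v
      ev <- draw_scr_events(cfg, vid, cond, sub_seed(cfg$seed, base_idx * 7 + 1))
      eda <- generate_eda_trace(ev, cfg$kernel_params, cfg$tonic_params,
                                cfg$eda_noise_sd, cfg$eda_rate,
                                cfg$duration_s,
                                seed = sub_seed(cfg$seed, base_idx * 7 + 2))
      pup <- generate_pupil_trace(cfg$pupil_baseline[[cond]],
                                  cfg$pupil_sigma_zeta[[cond]],
                                  cfg$pupil_noise_sd, cfg$blink_rate,
                                  cfg$pupil_rate, cfg$duration_s,
                                  seed = sub_seed(cfg$seed, base_idx * 7 + 3))
      joy <- generate_joystick_trace(cond, cfg$joystick_plateau[[cond]],
                                     cfg$joystick_rise_time_s,
                                     cfg$joystick_jitter_sd,
                                     cfg$joystick_rate, cfg$duration_s,
                                     seed = sub_seed(cfg$seed, base_idx * 7 + 4))
      for (tr in c("eda", "pup", "joy")) {
        obj <- get(tr)
        obj$participant <- participants[p]
        obj$video <- vid
        obj$condition <- cond
        assign(tr, obj)
      }
      traces[[p]][[vid]] <- list(eda = eda, pupil = pup, joystick = joy)
      if (nrow(ev)) {
        gt_events[[length(gt_events) + 1]] <-
          data.frame(participant = participants[p], video = vid,
                     condition = cond, onset = ev$time,
                     amplitude = ev$amplitude, stringsAsFactors = FALSE)
      }
      set.seed(sub_seed(cfg$seed, base_idx * 7 + 5))
      ratings <- rtruncnorm17(nrow(cfg$rating_means),
                              cfg$rating_means[, cond] + intercepts[p],
                              cfg$rating_sd)
      names(ratings) <- rownames(cfg$rating_means)
      trial_rows[[length(trial_rows) + 1]] <- data.frame(
        participant = participants[p], video = vid, condition = cond,
        order_within = owc[v],
        t(ratings),
        temperature = temperature[p], humidity = humidity[p],
        age = age[p], gender = gender[p], stringsAsFactors = FALSE)
    }
  }

  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  ground_truth <- list(
    events = if (length(gt_events)) do.call(rbind, gt_events) else
      data.frame(participant = character(), video = character(),
                 condition = character(), onset = numeric(),
                 amplitude = numeric(), stringsAsFactors = FALSE),
    pupil_sigma_zeta = cfg$pupil_sigma_zeta,
    joystick_plateau = cfg$joystick_plateau,
    rating_means = cfg$rating_means,
    intercepts = setNames(intercepts, participants)
  )
  list(traces = traces, trials = trials, ground_truth = ground_truth,
       config = cfg)
}
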