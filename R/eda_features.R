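#' Isolate the phasic component of an EDA trace
#'
#' Decimates the raw trace to a working rate (an anti-aliased moving-average
#' decimation) and applies a zero-phase 2nd-order Butterworth high-pass
#' filter. A very low cutoff (default 0.02 Hz) removes tonic level and slow
#' drift while leaving SCR morphology — which lives well below 1 Hz but above
#' ~0.05 Hz — essentially intact.
#'
#' @param trace an `eda_trace`.
#' @param highpass_hz high-pass cutoff (Hz), must be below the working
#'   Nyquist frequency. The default 0.02 Hz removes tonic drift while
#'   leaving the phasic kernel's half-recovery shape intact; higher cutoffs
#'   visibly shorten measured recovery times.
#' @param filter_order Butterworth order (default 2).
#' @param decimate_to working sampling rate in Hz (default 25); use `NULL`
#'   to filter at the original rate.
#' @return an `eda_trace` at the working rate containing the phasic signal.
#' @export
extract_phasic <- function(trace, highpass_hz = 0.02, filter_order = 2,
                           decimate_to = 25) {
  stopifnot(inherits(trace, "eda_trace"))
  x <- trace$values
  rate <- trace$rate
  if (!is.null(decimate_to) && decimate_to < rate) {
    q <- round(rate / decimate_to)
    x <- moving_average(x, q)
    x <- x[seq(1, length(x), by = q)]
    rate <- rate / q
  }
  stop_if_not(highpass_hz < rate / 2, "cutoff must be below Nyquist")
  stop_if_not(length(x) > 6 * filter_order, "trace too short to filter")
  # demean first: at these very low normalized cutoffs the filter's
  # numerical DC rejection is only ~1e-3, so remove the level exactly
  x <- x - mean(x)
  bf <- signal::butter(filter_order, highpass_hz / (rate / 2), type = "high")
  # reflect-pad by about one filter time constant so the zero-phase edge
  # transient (which spans tens of seconds at these cutoffs) falls outside
  # the analysed window
  np <- min(length(x) - 1L, ceiling(rate / highpass_hz))
  xp <- c(2 * x[1] - rev(x[2:(np + 1)]),
          x,
          2 * x[length(x)] - rev(x[(length(x) - np):(length(x) - 1)]))
  ph <- as.numeric(signal::filtfilt(bf, xp))[(np + 1):(np + length(x))]
  out <- trace
  out$values <- ph
  out$rate <- rate
  out
}

#' Detect skin conductance responses in a phasic signal
#'
#' Finds local maxima whose rise from the preceding local minimum (the
#' onset) is at least `min_amplitude`. For each event the amplitude is
#' peak minus onset level, rise time is onset to peak, and half-recovery
#' time is the first time after the peak at which the signal falls back to
#' the onset level plus half the amplitude — missing when that level is not
#' reached before the next event's onset or the end of the trace. Light
#' pre-smoothing (default 120 ms) suppresses noise-induced micro-peaks.
#'
#' @param phasic an `eda_trace` as returned by [extract_phasic()].
#' @param min_amplitude minimum rise in microsiemens (default 0.01, a common
#'   non-specific SCR criterion).
#' @param smooth_ms pre-smoothing window in ms (0 to disable).
#' @param max_rise_s maximum plausible onset-to-peak duration in seconds
#'   (default 8); slower rises are filter-rebound or drift artifacts, not
#'   SCRs, and are discarded.
#' @param onset_slope_frac onset refinement: the onset is the last sample
#'   before the steep rise whose slope is at most this fraction of the
#'   event's maximal rise slope (default 0.25). Prevents slow baseline
#'   recovery from being absorbed into the rise.
#' @return data.frame of class `scr_events`: one row per event with
#'   `onset_time`, `peak_time`, `amplitude`, `rise_time`,
#'   `half_recovery_time` (may be `NA`), sorted by onset.
#' @export
detect_scr_events <- function(phasic, min_amplitude = 0.01, smooth_ms = 120,
                              max_rise_s = 8, onset_slope_frac = 0.25) {
  stopifnot(inherits(phasic, "eda_trace"))
  x <- phasic$values
  rate <- phasic$rate
  empty <- data.frame(onset_time = numeric(), peak_time = numeric(),
                      amplitude = numeric(), rise_time = numeric(),
                      half_recovery_time = numeric())
  if (length(x) < 3) return(structure(empty, class = c("scr_events",
                                                       "data.frame")))
  if (smooth_ms > 0) x <- moving_average(x, round(smooth_ms / 1000 * rate))
  n <- length(x)
  d <- diff(x)
  sign_d <- sign(d)
  sign_d[sign_d == 0] <- 1  # plateaus: treat as rising so the first sample
                            # of a maximal plateau becomes the peak
  turns <- diff(sign_d)
  peaks <- which(turns < 0) + 1L
  troughs <- which(turns > 0) + 1L
  rows <- list()
  for (pk in peaks) {
    cand <- troughs[troughs < pk]
    trough_idx <- if (length(cand)) max(cand) else 1L
    # onset: start of the steep rise, not necessarily the trough itself —
    # slow baseline recovery (e.g. after filtering) can push the local
    # minimum far ahead of the response. Walk back from the peak to the
    # last sample whose slope is below a fraction of the event's maximal
    # rise slope.
    onset_idx <- trough_idx
    if (pk - trough_idx >= 2L) {
      seg_d <- d[trough_idx:(pk - 1L)]
      imax <- which.max(seg_d)
      slow <- which(seg_d[seq_len(imax)] <= onset_slope_frac * seg_d[imax])
      if (length(slow)) onset_idx <- trough_idx + max(slow) - 1L
    }
    amp <- x[pk] - x[onset_idx]
    if (!is.finite(amp) || amp < min_amplitude) next
    if ((pk - onset_idx) / rate > max_rise_s) next
    rows[[length(rows) + 1]] <- data.frame(
      onset_idx = onset_idx, peak_idx = pk,
      onset_time = (onset_idx - 1) / rate,
      peak_time = (pk - 1) / rate,
      amplitude = amp,
      rise_time = (pk - onset_idx) / rate)
  }
  if (!length(rows)) {
    return(structure(empty, class = c("scr_events", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_time), , drop = FALSE]
  # half-recovery: first time after the peak at which the signal falls to
  # onset level + amplitude/2, searched until the next event's onset (or
  # trace end); missing if the level is not reached in that window
  out$half_recovery_time <- NA_real_
  for (i in seq_len(nrow(out))) {
    pk <- out$peak_idx[i]
    half_level <- x[out$onset_idx[i]] + out$amplitude[i] / 2
    lim <- if (i < nrow(out)) out$onset_idx[i + 1] else n
    if (lim <= pk) next
    below <- which(x[(pk + 1):lim] <= half_level)
    if (length(below)) out$half_recovery_time[i] <- below[1] / rate
  }
  out$onset_idx <- out$peak_idx <- NULL
  rownames(out) <- NULL
  structure(out, class = c("scr_events", "data.frame"))
}

#' Drop SCRs that begin too early in the video
#'
#' Events whose onset occurs strictly before `min_onset_s` (default 10 s) are
#' removed, excluding responses driven by the start of the presentation
#' itself; an onset exactly at the boundary is kept.
#'
#' @param events an `scr_events` data.frame.
#' @param min_onset_s exclusion boundary in seconds.
#' @return the filtered events.
#' @export
apply_onset_exclusion <- function(events, min_onset_s = 10) {
  out <- events[events$onset_time >= min_onset_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trim outlying SCR measures and log-transform
#'
#' Pools one raw measure across the whole dataset, masks values lying
#' outside mean +/- `sd_limit` pooled SDs, and natural-log transforms the
#' rest. When the pooled SD is zero nothing is trimmed.
#'
#' @param values numeric vector of pooled raw measure values (amplitude,
#'   rise time, or half-recovery time); `NA` allowed and ignored.
#' @param sd_limit trimming limit in pooled SD units (default 3).
#' @return list with `log_values` (`NA` where trimmed or input was `NA`),
#'   `trimmed` (logical mask) and the pooled `mean`/`sd` used.
#' @export
trim_and_transform <- function(values, sd_limit = 3) {
  ok <- !is.na(values)
  stop_if_not(sum(ok) >= 1, "no observed values to transform")
  m <- mean(values[ok])
  s <- if (sum(ok) >= 2) sd(values[ok]) else 0
  trimmed <- ok & s > 0 & abs(values - m) > sd_limit * s
  lv <- ifelse(ok & !trimmed, log(values), NA_real_)
  list(log_values = lv, trimmed = trimmed & !is.na(trimmed), mean = m, sd = s)
}

#' Per-trial SCR feature summary
#'
#' Summarises retained (post-exclusion, post-trimming) events of one
#' participant x video cell into the four SCR indices: event count over the
#' analysis window and means of the log-transformed amplitude, rise time and
#' half-recovery time. A measure with no contributing events is missing.
#'
#' @param events data.frame with `onset_time`, `peak_time` and log-measure
#'   columns `log_amplitude`, `log_rise`, `log_recovery` (`NA` where trimmed
#'   or unobserved).
#' @param window counting window (s), default `c(10, 120)`; peaks in
#'   `[window[1], window[2])` are counted.
#' @return one-row data.frame: `n_scrs`, `mean_log_amplitude`,
#'   `mean_log_rise`, `mean_log_recovery`, `n_trimmed`.
#' @export
summarize_features <- function(events, window = c(10, 120)) {
  inw <- events$peak_time >= window[1] & events$peak_time < window[2]
  ev <- events[inw, , drop = FALSE]
  mn <- function(v) if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
  n_trim <- sum(vapply(c("log_amplitude", "log_rise", "log_recovery"),
                       function(cl) sum(is.na(ev[[cl]])), numeric(1)))
  data.frame(n_scrs = nrow(ev),
             mean_log_amplitude = mn(ev$log_amplitude),
             mean_log_rise = mn(ev$log_rise),
             mean_log_recovery = mn(ev$log_recovery),
             n_trimmed = n_trim)
}

#' Per-second SCR peak counts
#'
#' Counts event peaks in half-open 1-s bins over the analysis window
#' (default `[10, 120)` s -> 110 bins), the input grid of the group-level
#' SCR time series.
#'
#' @param events an `scr_events` data.frame (onset exclusion applied).
#' @param window counting window (s).
#' @param bin bin width (s), default 1.
#' @return integer vector of per-bin counts, length
#'   `(window[2] - window[1]) / bin`.
#' @export
bin_scr_counts <- function(events, window = c(10, 120), bin = 1) {
  edges <- seq(window[1], window[2], by = bin)
  n_bins <- length(edges) - 1L
  pk <- events$peak_time
  pk <- pk[pk >= window[1] & pk < window[2]]
  if (!length(pk)) return(integer(n_bins))
  idx <- floor((pk - window[1]) / bin) + 1L
  tabulate(idx, nbins = n_bins)
}

#' Full SCR feature pipeline for a set of EDA traces
#'
#' Convenience wrapper: phasic extraction, event detection, onset exclusion,
#' dataset-pooled trimming + log transform, per-trial summaries and
#' per-second count vectors.
#'
#' @param traces list of `eda_trace` objects (with participant/video/
#'   condition labels set).
#' @param min_amplitude,highpass_hz,min_onset_s,sd_limit,window see the
#'   individual steps.
#' @return list with `events` (all retained events, labelled), `features`
#'   (one row per trace) and `counts` (list of per-trace count vectors).
#' @export
eda_feature_pipeline <- function(traces, min_amplitude = 0.01,
                                 highpass_hz = 0.02, min_onset_s = 10,
                                 sd_limit = 3, window = c(10, 120)) {
  evs <- lapply(traces, function(tr) {
    ph <- extract_phasic(tr, highpass_hz = highpass_hz)
    ev <- apply_onset_exclusion(detect_scr_events(ph, min_amplitude),
                                min_onset_s)
    if (nrow(ev)) {
      ev$participant <- tr$participant
      ev$video <- tr$video
      ev$condition <- tr$condition
    }
    ev
  })
  all_ev <- do.call(rbind, evs[vapply(evs, nrow, integer(1)) > 0])
  if (is.null(all_ev)) {
    all_ev <- data.frame(onset_time = numeric(), peak_time = numeric(),
                         amplitude = numeric(), rise_time = numeric(),
                         half_recovery_time = numeric(),
                         participant = character(), video = character(),
                         condition = character(), stringsAsFactors = FALSE)
  }
  if (nrow(all_ev)) {
    all_ev$log_amplitude <- trim_and_transform(all_ev$amplitude,
                                               sd_limit)$log_values
    all_ev$log_rise <- trim_and_transform(all_ev$rise_time,
                                          sd_limit)$log_values
    all_ev$log_recovery <-
      trim_and_transform(all_ev$half_recovery_time, sd_limit)$log_values
  } else {
    all_ev$log_amplitude <- all_ev$log_rise <- all_ev$log_recovery <-
      numeric(0)
  }
  feats <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    sel <- all_ev$participant == tr$participant & all_ev$video == tr$video
    f <- summarize_features(all_ev[which(sel), , drop = FALSE], window)
    cbind(data.frame(participant = tr$participant, video = tr$video,
                     condition = tr$condition, stringsAsFactors = FALSE), f)
  })
  counts <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    sel <- all_ev$participant == tr$participant & all_ev$video == tr$video
    bin_scr_counts(all_ev[which(sel), , drop = FALSE], window)
  })
  list(events = all_ev, features = do.call(rbind, feats), counts = counts)
}
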