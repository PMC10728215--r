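#' Detect blink and artifact samples in a pupil trace
#'
#' Flags samples that are missing, non-positive, or adjacent to diameter
#' excursions faster than `velocity_limit`, and extends each flagged span by
#' `pad_ms` on both sides (blink on/offsets distort the signal beyond the
#' dropout itself).
#'
#' @param trace a `pupil_trace`.
#' @param velocity_limit maximum plausible diameter change in mm/s
#'   (default 10).
#' @param pad_ms padding applied to each side of a flagged span (default 50).
#' @return logical blink mask, same length as the trace.
#' @export
detect_blinks <- function(trace, velocity_limit = 10, pad_ms = 50) {
  stopifnot(inherits(trace, "pupil_trace"))
  x <- trace$values
  rate <- trace$rate
  mask <- is.na(x) | (!is.na(x) & x <= 0)
  v <- c(0, diff(x)) * rate
  fast <- !is.na(v) & abs(v) > velocity_limit
  mask <- mask | fast | c(fast[-1], FALSE)
  pad <- round(pad_ms / 1000 * rate)
  if (pad > 0 && any(mask)) {
    idx <- which(mask)
    ext <- unique(unlist(lapply(idx, function(i) (i - pad):(i + pad))))
    ext <- ext[ext >= 1 & ext <= length(x)]
    mask[ext] <- TRUE
  }
  mask
}

#' Fraction of masked samples and the exclusion decision
#'
#' @param trace a `pupil_trace`.
#' @param mask blink mask (defaults to [detect_blinks()] output).
#' @param max_missing exclusion threshold on the missing fraction
#'   (default 0.10: a trace with more than 10% missing data flags its
#'   participant for exclusion).
#' @return list with `fraction` and logical `exclude`.
#' @export
missing_fraction <- function(trace, mask = detect_blinks(trace),
                             max_missing = 0.10) {
  f <- mean(mask)
  list(fraction = f, exclude = f > max_missing)
}

#' Interpolate masked spans of a pupil trace
#'
#' Masked spans are replaced by linear interpolation between the flanking
#' valid samples; leading/trailing gaps take the nearest valid value.
#'
#' @param trace a `pupil_trace`.
#' @param mask logical mask of samples to replace.
#' @return the trace with `values` gap-free and `blink_mask` set to `mask`.
#' @export
interpolate_gaps <- function(trace, mask = detect_blinks(trace)) {
  stopifnot(inherits(trace, "pupil_trace"))
  x <- trace$values
  x[mask] <- NA_real_
  ok <- which(!is.na(x))
  stop_if_not(length(ok) >= 1, "trace has no valid samples to interpolate from")
  if (length(ok) < length(x)) {
    x <- approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
  }
  out <- trace
  out$values <- x
  out$blink_mask <- mask
  out
}

#' Smooth a gap-free trace with a centered moving average
#'
#' @param trace an `awedyn_trace` without missing values.
#' @param window_ms smoothing window in ms (default 100); a window shorter
#'   than one sample leaves the trace unchanged. Edges use a shrinking
#'   window.
#' @return the smoothed trace.
#' @export
smooth_trace <- function(trace, window_ms = 100) {
  stopifnot(inherits(trace, "awedyn_trace"))
  stop_if_not(!anyNA(trace$values), "interpolate before smoothing")
  k <- round(window_ms / 1000 * trace$rate)
  out <- trace
  out$values <- moving_average(trace$values, k)
  out
}

#' Resample a cleaned trace to the 1-Hz analysis grid
#'
#' The value at second `t` is the mean of samples in the half-open bin
#' `[t, t+1)`; a trace covering `[0, 120)` s yields 120 values.
#'
#' @param trace a gap-free `awedyn_trace` (pupil or joystick).
#' @return an `observed_series`: list with `values`, `grid` (bin start
#'   times), `source`, and the trace labels.
#' @export
to_second_series <- function(trace) {
  stopifnot(inherits(trace, "awedyn_trace"))
  x <- trace$values
  stop_if_not(!anyNA(x), "trace must be gap-free")
  rate <- trace$rate
  n_sec <- floor(length(x) / rate)
  stop_if_not(n_sec >= 1, "trace shorter than one second")
  tt <- floor((seq_along(x) - 1) / rate)
  keep <- tt < n_sec
  vals <- as.numeric(tapply(x[keep], tt[keep], mean))
  structure(list(values = vals, grid = seq_len(n_sec) - 1,
                 source = sub("_trace$", "", class(trace)[1]),
                 participant = trace$participant, video = trace$video,
                 condition = trace$condition),
            class = "observed_series")
}

#' @export
print.observed_series <- function(x, ...) {
  cat(sprintf("<observed_series:%s> video=%s condition=%s, length %d\n",
              x$source, x$video, x$condition, length(x$values)))
  invisible(x)
}

#' Pointwise group average of per-participant series
#'
#' Averages 1-Hz series (or SCR count vectors) across retained participants
#' for one video, producing the group-level series the state-space model is
#' fitted to.
#'
#' @param series_list non-empty list of `observed_series` or plain numeric
#'   vectors of equal length.
#' @return an `observed_series` with the pointwise mean.
#' @export
group_average <- function(series_list) {
  stop_if_not(length(series_list) >= 1, "need at least one participant series")
  vals <- lapply(series_list, function(s)
    if (inherits(s, "observed_series")) s$values else as.numeric(s))
  len <- vapply(vals, length, integer(1))
  stop_if_not(length(unique(len)) == 1L, "series lengths differ")
  avg <- Reduce(`+`, vals) / length(vals)
  tmpl <- series_list[[1]]
  structure(list(values = avg,
                 grid = if (inherits(tmpl, "observed_series")) tmpl$grid
                        else seq_along(avg) - 1,
                 source = if (inherits(tmpl, "observed_series")) tmpl$source
                          else "scr_count",
                 participant = NA,
                 video = if (inherits(tmpl, "observed_series")) tmpl$video
                         else NA,
                 condition = if (inherits(tmpl, "observed_series"))
                   tmpl$condition else NA),
            class = "observed_series")
}

#' Full pupil preprocessing pipeline for one trace
#'
#' De-blinking, missingness check, interpolation, smoothing and 1-Hz
#' resampling in one call.
#'
#' @param trace a `pupil_trace`.
#' @param velocity_limit,pad_ms see [detect_blinks()].
#' @param window_ms see [smooth_trace()].
#' @param max_missing see [missing_fraction()].
#' @return list with `series` (an `observed_series`, or `NULL` if excluded),
#'   `fraction` missing, and logical `exclude`.
#' @export
pupil_preprocess_pipeline <- function(trace, velocity_limit = 10,
                                      pad_ms = 50, window_ms = 100,
                                      max_missing = 0.10) {
  mask <- detect_blinks(trace, velocity_limit, pad_ms)
  mf <- missing_fraction(trace, mask, max_missing)
  if (mf$exclude) {
    return(list(series = NULL, fraction = mf$fraction, exclude = TRUE))
  }
  cleaned <- smooth_trace(interpolate_gaps(trace, mask), window_ms)
  list(series = to_second_series(cleaned), fraction = mf$fraction,
       exclude = FALSE)
}
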