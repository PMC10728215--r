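#' Derive a deterministic sub-seed from a master seed
#'
#' Used to give every participant x video x signal its own reproducible
#' random stream while the whole session is driven by one master seed.
#'
#' @param master integer master seed.
#' @param index integer stream index (>= 1).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
sub_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(index) * 16807
  as.integer(s %% (m - 1) + 1)
}

#' Centered moving average with shrinking edge windows
#'
#' @param x numeric vector (no missing values).
#' @param k odd window length in samples; even values are rounded up.
#' @return smoothed vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Equal-tailed credible interval and posterior mean of a draw vector
#' @keywords internal
post_summary <- function(draws, prob = 0.95) {
  a <- (1 - prob) / 2
  ci <- unname(quantile(draws, c(a, 1 - a), names = FALSE))
  list(eap = mean(draws), lower = ci[1], upper = ci[2],
       significant = ci[1] > 0 || ci[2] < 0)
}

#' Slice sampler for a univariate log-density (stepping out + shrinkage)
#'
#' @param x0 current value.
#' @param logf log target density function.
#' @param w initial bracket width.
#' @param lower,upper hard support bounds.
#' @return a new sample from the target.
#' @keywords internal
slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50L) {
  f0 <- logf(x0)
  z <- f0 - stats::rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  s <- 0L
  while (L > lower && logf(L) > z && s < max_steps) { L <- L - w; s <- s + 1L }
  s <- 0L
  while (R < upper && logf(R) > z && s < max_steps) { R <- R + w; s <- s + 1L }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
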