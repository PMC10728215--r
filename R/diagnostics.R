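#' MCMC convergence diagnostics
#'
#' Rank-normalized split R-hat and bulk/tail effective sample sizes, computed
#' from a draws matrix with one column per chain. These follow the now
#' standard definitions: chains are split in half, draws are rank-normalized
#' through the inverse normal CDF, R-hat is the usual between/within variance
#' ratio on the transformed draws, and ESS is obtained from chain-averaged
#' autocorrelations truncated by Geyer's initial monotone positive sequence.
#' Tail ESS is the smaller ESS of the 5% and 95% exceedance indicators.
#'
#' @param draws numeric matrix, iterations x chains (>= 1 chain). With a
#'   single chain the split halves play the role of two chains, i.e. split
#'   R-hat is still defined.
#' @return `rhat()` a scalar; `ess_bulk()`/`ess_tail()` scalars.
#' @name diagnostics
NULL

split_chains <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  h <- n %/% 2L
  if (h < 2L) return(draws)
  cbind(draws[seq_len(h), , drop = FALSE],
        draws[(n - h + 1L):n, , drop = FALSE])
}

rank_normalize <- function(draws) {
  r <- rank(as.vector(draws), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(draws), ncol = ncol(draws))
}

rhat_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4L || m < 2L) return(NA_real_)
  mu_j <- colMeans(draws)
  s2_j <- apply(draws, 2, var)
  W <- mean(s2_j)
  B <- n * var(mu_j)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname diagnostics
#' @export
rhat <- function(draws) {
  sp <- split_chains(as.matrix(draws))
  if (ncol(sp) < 2L) return(NA_real_)
  if (all(abs(sp - sp[1]) < 1e-300)) return(1)
  max(rhat_basic(rank_normalize(sp)),
      rhat_basic(rank_normalize(abs(sp - median(sp)))))
}

ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4L) return(NA_real_)
  chain_var <- apply(draws, 2, var)
  if (all(chain_var < 1e-300)) return(NA_real_)
  W <- mean(chain_var)
  B <- if (m > 1L) n * var(colMeans(draws)) else 0
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- min(n - 1L, 400L)
  rho_ch <- sapply(seq_len(m), function(j) {
    a <- acf(draws[, j], lag.max = max_lag, plot = FALSE,
             demean = TRUE)$acf[-1]
    a * chain_var[j]
  })
  rho_ch <- matrix(rho_ch, nrow = max_lag)
  rho <- 1 - (W - rowMeans(rho_ch)) / var_plus
  # Geyer initial monotone positive sequence on paired autocorrelations:
  # P_0 = 1 + rho_1, P_k = rho_2k + rho_2k+1; truncate at the first
  # non-positive pair and enforce monotone non-increasing partial sums.
  np <- max_lag %/% 2L
  P <- 1 + rho[1]
  if (np >= 2L) {
    P <- c(P, rho[2 * seq_len(np - 1L)] + rho[2 * seq_len(np - 1L) + 1L])
  }
  P <- P[!is.na(P)]
  tot <- 0
  prev <- Inf
  for (p in P) {
    if (p <= 0) break
    p <- min(p, prev)
    tot <- tot + p
    prev <- p
  }
  tau <- max(2 * tot - 1, 1 / log10(n * m + 10))
  min(n * m / tau, n * m)
}

#' @rdname diagnostics
#' @export
ess_bulk <- function(draws) {
  sp <- split_chains(as.matrix(draws))
  ess_basic(rank_normalize(sp))
}

#' @rdname diagnostics
#' @export
ess_tail <- function(draws) {
  sp <- split_chains(as.matrix(draws))
  q05 <- quantile(as.vector(sp), 0.05, names = FALSE)
  q95 <- quantile(as.vector(sp), 0.95, names = FALSE)
  e1 <- ess_basic(1 * (sp <= q05))
  e2 <- ess_basic(1 * (sp <= q95))
  min(e1, e2)
}

#' Diagnostics table for a set of named draw matrices
#'
#' @param draw_list named list of iterations x chains matrices.
#' @param rhat_limit,ess_limit pass/fail thresholds (defaults 1.10 and 1000).
#' @return data.frame with one row per parameter: R-hat, bulk and tail ESS,
#'   and logical pass flags.
#' @export
diagnostics_table <- function(draw_list, rhat_limit = 1.10, ess_limit = 1000) {
  rows <- lapply(names(draw_list), function(nm) {
    d <- as.matrix(draw_list[[nm]])
    r <- rhat(d); eb <- ess_bulk(d); et <- ess_tail(d)
    data.frame(parameter = nm, rhat = r, ess_bulk = eb, ess_tail = et,
               rhat_ok = is.na(r) | r < rhat_limit,
               ess_ok = !is.na(eb) && !is.na(et) &&
                 eb > ess_limit && et > ess_limit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
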