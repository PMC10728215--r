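#' Build the design matrix for a condition-contrast model
#'
#' Implements the study's coding: awe contrast (awe = 2/3, others = -1/3),
#' amusement contrast (amusement = 2/3, others = -1/3), session covariates
#' (temperature, humidity, centered), and the model-variant terms:
#' `"control"` adds amusement and fear ratings as covariates, `"order"` adds
#' contrast x presentation-order interactions (first = -1/2, second = +1/2),
#' `"demographic"` adds centered age and gender (+/- 1/2) with their
#' awe-contrast interactions.
#'
#' @param records data.frame of trial records (one row per participant x
#'   video) with columns `participant`, `condition`, the outcome, and the
#'   covariates the variant needs.
#' @param outcome name of the outcome column.
#' @param variant one of `"simple"`, `"control"`, `"order"`,
#'   `"demographic"`.
#' @param contrasts which condition contrasts to include: `"both"`
#'   (default, the study's model; note that with both columns present the
#'   awe coefficient equals the awe-neutral mean difference) or `"awe"` /
#'   `"amusement"` alone (the single-contrast coefficient equals the
#'   condition-versus-others mean difference).
#' @param covariates session covariates included as fixed effects
#'   (default temperature and humidity; set `character(0)` to drop).
#' @return list with `X` (design matrix), `y`, `group` (participant factor),
#'   and `terms`.
#' @export
build_design <- function(records, outcome,
                         variant = c("simple", "control", "order",
                                     "demographic"),
                         covariates = c("temperature", "humidity"),
                         contrasts = c("both", "awe", "amusement")) {
  variant <- match.arg(variant)
  contrasts <- match.arg(contrasts)
  stop_if_not(outcome %in% names(records),
              paste("outcome column not found:", outcome))
  stop_if_not(all(records$condition %in% c("neutral", "amusement", "awe")),
              "unknown condition label")
  y <- records[[outcome]]
  awe_c <- ifelse(records$condition == "awe", 2 / 3, -1 / 3)
  amu_c <- ifelse(records$condition == "amusement", 2 / 3, -1 / 3)
  X <- switch(contrasts,
    both = cbind(`(Intercept)` = 1, awe_contrast = awe_c,
                 amusement_contrast = amu_c),
    awe = cbind(`(Intercept)` = 1, awe_contrast = awe_c),
    amusement = cbind(`(Intercept)` = 1, amusement_contrast = amu_c))
  for (cv in covariates) {
    stop_if_not(cv %in% names(records), paste("missing covariate:", cv))
    X <- cbind(X, scale(records[[cv]], scale = FALSE)[, 1])
    colnames(X)[ncol(X)] <- cv
  }
  if (variant == "control") {
    for (cv in c("amusement", "fear")) {
      stop_if_not(cv %in% names(records),
                  paste("control variant needs rating column:", cv))
      X <- cbind(X, scale(records[[cv]], scale = FALSE)[, 1])
      colnames(X)[ncol(X)] <- paste0(cv, "_rating")
    }
  } else if (variant == "order") {
    stop_if_not("order_within" %in% names(records),
                "order variant needs order_within (1/2) column")
    ord <- ifelse(records$order_within == 1, -1 / 2, 1 / 2)
    X <- cbind(X, order = ord, `awe_contrast:order` = awe_c * ord,
               `amusement_contrast:order` = amu_c * ord)
  } else if (variant == "demographic") {
    stop_if_not(all(c("age", "gender") %in% names(records)),
                "demographic variant needs age and gender columns")
    age_c <- scale(records$age, scale = FALSE)[, 1]
    gen <- ifelse(records$gender %in% c("f", "female", "F"), -1 / 2, 1 / 2)
    X <- cbind(X, age = age_c, gender = gen,
               `awe_contrast:age` = awe_c * age_c,
               `awe_contrast:gender` = awe_c * gen)
  }
  # reject singular designs with named culprits
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is singular; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(X = X, y = y, group = factor(records$participant),
       terms = colnames(X), outcome = outcome, variant = variant)
}

# one Gibbs run for y = X beta + u[group] + e; group = NULL -> plain
# Bayesian linear regression
gibbs_lmm <- function(X, y, group, iter, warmup, prior_beta_sd,
                      prior_sd_scale) {
  n <- length(y); p <- ncol(X)
  intercept_col <- match("(Intercept)", colnames(X), nomatch = 0L)
  has_u <- !is.null(group)
  if (has_u) {
    g <- as.integer(group)
    J <- max(g)
    nj <- tabulate(g, J)
  }
  XtX <- crossprod(X)
  prior_prec <- diag(1 / prior_beta_sd^2, p)
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  u <- if (has_u) numeric(J) else NULL
  sigma <- max(sd(y - X %*% beta), 1e-3)
  tau <- if (has_u) sigma / 2 else NULL
  kept <- iter - warmup
  out_beta <- matrix(NA_real_, kept, p)
  out_sd <- matrix(NA_real_, kept, if (has_u) 2 else 1)
  log_sd_post <- function(th, ss, nn, sc) {
    -nn * th - ss / 2 * exp(-2 * th) - exp(2 * th) / (2 * sc^2) + th
  }
  for (i in seq_len(iter)) {
    uvec <- if (has_u) u[g] else 0
    # beta | .
    V <- chol2inv(chol(XtX / sigma^2 + prior_prec))
    m <- V %*% (crossprod(X, y - uvec) / sigma^2)
    beta <- as.numeric(m + t(chol(V)) %*% rnorm(p))
    resid0 <- y - as.numeric(X %*% beta)
    if (has_u) {
      # u | .
      prec <- nj / sigma^2 + 1 / tau^2
      mu_u <- as.numeric(rowsum(resid0, g)) / sigma^2 / prec
      u <- rnorm(J, mu_u, sqrt(1 / prec))
      # recenter along the (intercept + c, u - c) ridge: draw the shift
      # from its full conditional (priors only) to decorrelate the
      # intercept from the random-intercept mean
      if (intercept_col > 0) {
        prec_c <- J / tau^2 + 1 / prior_beta_sd^2
        mean_c <- (sum(u) / tau^2 - beta[intercept_col] / prior_beta_sd^2) /
          prec_c
        cshift <- rnorm(1, mean_c, sqrt(1 / prec_c))
        u <- u - cshift
        beta[intercept_col] <- beta[intercept_col] + cshift
      }
      uvec <- u[g]
      # tau | .
      th <- slice_sample1(log(tau), function(t)
        log_sd_post(t, sum(u^2), J, prior_sd_scale), w = 0.5,
        lower = log(1e-8), upper = log(1e6))
      tau <- exp(th)
    }
    ee <- resid0 - if (has_u) uvec else 0
    th <- slice_sample1(log(sigma), function(t)
      log_sd_post(t, sum(ee^2), n, prior_sd_scale), w = 0.5,
      lower = log(1e-8), upper = log(1e6))
    sigma <- exp(th)
    if (i > warmup) {
      out_beta[i - warmup, ] <- beta
      out_sd[i - warmup, ] <- if (has_u) c(sigma, tau) else sigma
    }
  }
  list(beta = out_beta, sd = out_sd)
}

#' Fit a hierarchical Bayesian contrast model
#'
#' Gaussian linear mixed model
#' \eqn{y = X\beta + u_{participant} + e}, \eqn{u \sim N(0, \tau^2)},
#' \eqn{e \sim N(0, \sigma^2)}, with weakly-informative priors
#' (Normal(0, 10 sd(y)) on each coefficient, half-Normal on both SDs),
#' sampled by a blocked Gibbs sampler (conjugate normal updates for
#' \eqn{\beta} and \eqn{u}; slice updates for the SDs on the log scale).
#'
#' @param design output of [build_design()] (or a compatible list with `X`,
#'   `y`, `group`; `group = NULL` gives a plain Bayesian regression).
#' @param chains,iter,warmup sampler configuration (defaults 4 x 2000 with
#'   1000 warmup; `paper_scale = TRUE` uses 4 x 20000 with 10000 warmup).
#' @param seed integer seed.
#' @param paper_scale use the long sampler configuration.
#' @return object of class `contrast_fit`: `draws` (named list of
#'   iterations x chains matrices per term plus `sigma` and, when grouped,
#'   `tau`), `table` (EAP, 95% CI, significance), `diagnostics`,
#'   `converged`.
#' @export
fit_hier <- function(design, chains = 4, iter = 2000,
                     warmup = floor(iter / 2), seed = 1L,
                     paper_scale = FALSE) {
  if (paper_scale) { chains <- 4; iter <- 20000; warmup <- 10000 }
  X <- design$X; y <- design$y; group <- design$group
  stop_if_not(!anyNA(y), "outcome contains missing values; impute first")
  if (!is.null(group)) {
    stop_if_not(nlevels(factor(group)) >= 2, "need at least 2 participants")
  }
  sdy <- max(sd(y), 1e-6)
  set.seed(as.integer(seed))
  kept <- iter - warmup
  p <- ncol(X)
  runs <- lapply(seq_len(chains), function(cc) {
    gibbs_lmm(X, y, group, iter, warmup,
              prior_beta_sd = 10 * sdy, prior_sd_scale = 2.5 * sdy)
  })
  draws <- list()
  for (j in seq_len(p)) {
    draws[[colnames(X)[j]]] <-
      vapply(runs, function(r) r$beta[, j], numeric(kept))
  }
  draws$sigma <- vapply(runs, function(r) r$sd[, 1], numeric(kept))
  if (!is.null(group)) {
    draws$tau <- vapply(runs, function(r) r$sd[, 2], numeric(kept))
  }
  build_contrast_fit(draws, design,
                     config = list(chains = chains, iter = iter,
                                   warmup = warmup, seed = as.integer(seed)))
}

build_contrast_fit <- function(draws, design, config) {
  tab <- do.call(rbind, lapply(names(draws), function(nm) {
    s <- post_summary(as.vector(draws[[nm]]))
    data.frame(term = nm, eap = s$eap, lower = s$lower, upper = s$upper,
               significant = s$significant, stringsAsFactors = FALSE)
  }))
  diag_tab <- diagnostics_table(draws)
  structure(list(draws = draws, table = tab, diagnostics = diag_tab,
                 converged = all(diag_tab$rhat_ok, na.rm = TRUE),
                 outcome = design$outcome %||% NA,
                 variant = design$variant %||% NA,
                 terms = design$terms %||% names(draws),
                 config = config),
            class = "contrast_fit")
}

#' @export
print.contrast_fit <- function(x, ...) {
  cat(sprintf("Hierarchical contrast model: outcome = %s (variant: %s)\n",
              x$outcome, x$variant))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s %8.3f  [%7.3f, %7.3f]%s\n", tab$term[i],
                tab$eap[i], tab$lower[i], tab$upper[i],
                if (tab$significant[i] && !tab$term[i] %in%
                    c("(Intercept)", "sigma", "tau")) " *" else ""))
  }
  cat(sprintf("  converged: %s\n", if (x$converged) "yes" else "NO"))
  invisible(x)
}

#' @export
summary.contrast_fit <- function(object, ...) {
  merge(object$table, object$diagnostics,
        by.x = "term", by.y = "parameter", sort = FALSE)
}

#' @export
coef.contrast_fit <- function(object, ...) {
  b <- object$table[object$table$term %in% object$terms, ]
  setNames(b$eap, b$term)
}

#' Multiple imputation by chained equations (normal linear engine)
#'
#' Imputes missing values by cycling Bayesian normal linear imputation
#' models over the incomplete variables: at each visit the imputation
#' model's coefficients and residual SD are drawn from their posterior given
#' the currently completed data, and the missing entries are drawn from the
#' resulting predictive distribution. Predictors are all other supplied
#' analysis variables.
#'
#' @param records data.frame; missingness is expected in the numeric
#'   analysis columns only.
#' @param vars character: the analysis variables entering the imputation
#'   models (default: all numeric columns).
#' @param m number of imputed data sets (study default 100).
#' @param maxit chained-equation cycles per imputation (default 10).
#' @param seed integer seed.
#' @return list of `m` completed data.frames, each carrying an
#'   `"imputation"` attribute with its index.
#' @export
impute_missing <- function(records, vars = NULL, m = 100, maxit = 10,
                           seed = 1L) {
  if (is.null(vars)) {
    vars <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  miss_vars <- vars[vapply(vars, function(v) anyNA(records[[v]]), logical(1))]
  for (v in miss_vars) {
    stop_if_not(any(!is.na(records[[v]])),
                paste("variable has no observed values:", v))
  }
  if (!length(miss_vars)) {
    return(lapply(seq_len(m), function(i) {
      attr(records, "imputation") <- i
      records
    }))
  }
  set.seed(as.integer(seed))
  lapply(seq_len(m), function(i) {
    d <- records
    # initial fill: random draws from the observed margins
    for (v in miss_vars) {
      na_idx <- which(is.na(d[[v]]))
      d[[v]][na_idx] <- sample(d[[v]][!is.na(d[[v]])], length(na_idx),
                               replace = TRUE)
    }
    for (cycle in seq_len(maxit)) {
      for (v in miss_vars) {
        na_idx <- which(is.na(records[[v]]))
        preds <- setdiff(vars, v)
        Xall <- as.matrix(cbind(1, d[preds]))
        obs <- setdiff(seq_len(nrow(d)), na_idx)
        Xo <- Xall[obs, , drop = FALSE]
        yo <- d[[v]][obs]
        qrX <- qr(Xo)
        keep <- qrX$pivot[seq_len(qrX$rank)]
        Xo <- Xo[, keep, drop = FALSE]
        Xm <- Xall[na_idx, keep, drop = FALSE]
        # Bayesian draw of (beta, sigma) under a flat prior
        fit <- lm.fit(Xo, yo)
        df <- max(length(yo) - ncol(Xo), 1)
        s2 <- sum(fit$residuals^2) / df
        sigma2 <- df * s2 / stats::rchisq(1, df)
        XtXi <- chol2inv(chol(crossprod(Xo) +
                                diag(1e-8, ncol(Xo))))
        beta <- as.numeric(fit$coefficients) +
          as.numeric(t(chol(sigma2 * XtXi)) %*% rnorm(ncol(Xo)))
        d[[v]][na_idx] <- as.numeric(Xm %*% beta) +
          rnorm(length(na_idx), 0, sqrt(sigma2))
      }
    }
    attr(d, "imputation") <- i
    d
  })
}

#' Pooled Bayesian regression over imputed data sets
#'
#' Fits the model to each completed data set and pools by stacking the
#' posterior draws across imputations, so the pooled posterior reflects both
#' within- and between-imputation uncertainty.
#'
#' @param imputed list of completed data.frames (see [impute_missing()]).
#' @param outcome outcome column name.
#' @param predictors character vector of predictor columns.
#' @param hierarchical include a participant random intercept
#'   (default `FALSE`: plain Bayesian GLM, as in per-condition regressions).
#' @param chains,iter,warmup,seed sampler configuration per imputation
#'   (defaults 2 x 1000 with 500 warmup per imputed set; total stacked draws
#'   = m x chains x (iter - warmup)).
#' @return a `contrast_fit` whose draw matrices stack imputations
#'   column-wise.
#' @export
fit_regression_pooled <- function(imputed, outcome, predictors,
                                  hierarchical = FALSE, chains = 2,
                                  iter = 1000, warmup = floor(iter / 2),
                                  seed = 1L) {
  stop_if_not(length(imputed) >= 1, "need at least one completed data set")
  fits <- lapply(seq_along(imputed), function(i) {
    d <- imputed[[i]]
    X <- cbind(`(Intercept)` = 1, as.matrix(d[, predictors, drop = FALSE]))
    colnames(X) <- c("(Intercept)", predictors)
    des <- list(X = X, y = d[[outcome]],
                group = if (hierarchical) factor(d$participant) else NULL,
                terms = colnames(X), outcome = outcome, variant = "pooled")
    fit_hier(des, chains = chains, iter = iter, warmup = warmup,
             seed = sub_seed(seed, i))
  })
  nms <- names(fits[[1]]$draws)
  draws <- setNames(lapply(nms, function(nm) {
    do.call(cbind, lapply(fits, function(f) f$draws[[nm]]))
  }), nms)
  des <- list(X = NULL, y = NULL, group = NULL,
              terms = fits[[1]]$terms, outcome = outcome,
              variant = "pooled")
  out <- build_contrast_fit(draws, des,
                            config = list(m = length(imputed),
                                          chains = chains, iter = iter,
                                          warmup = warmup,
                                          seed = as.integer(seed)))
  out
}

#' Results table for a set of contrast fits
#'
#' One row per (outcome, term): EAP, 95% CI bounds, R-hat, bulk/tail ESS and
#' the significance flag — the layout of the study-style results table.
#'
#' @param fits list of `contrast_fit` objects (possibly empty).
#' @param terms optional subset of terms to report (default: contrast terms).
#' @return data.frame.
#' @export
summarize_fits <- function(fits, terms = NULL) {
  if (!length(fits)) {
    return(data.frame(outcome = character(), term = character(),
                      eap = numeric(), lower = numeric(), upper = numeric(),
                      rhat = numeric(), ess_bulk = numeric(),
                      ess_tail = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(fits, function(f) {
    tt <- terms %||% setdiff(f$terms, "(Intercept)")
    tab <- merge(f$table[f$table$term %in% tt, ],
                 f$diagnostics, by.x = "term", by.y = "parameter",
                 sort = FALSE)
    data.frame(outcome = f$outcome, term = tab$term, eap = tab$eap,
               lower = tab$lower, upper = tab$upper, rhat = tab$rhat,
               ess_bulk = tab$ess_bulk, ess_tail = tab$ess_tail,
               significant = tab$significant, stringsAsFactors = FALSE)
  }))
}
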