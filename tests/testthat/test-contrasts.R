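test_that("design matrix implements the study's codings", {
  set.seed(2)
  rec <- make_balanced_records(8, seed = 2)
  rec$order_within <- rep(c(1, 2), 24)
  rec$age <- rep(round(rnorm(8, 21, 3)), each = 6)
  rec$gender <- rep(rep(c("f", "m"), 4), each = 6)

  d <- build_design(rec, "y")
  awe_rows <- rec$condition == "awe"
  expect_true(all(d$X[awe_rows, "awe_contrast"] == 2 / 3))
  expect_true(all(d$X[awe_rows, "amusement_contrast"] == -1 / 3))
  # contrasts sum to zero over one participant's balanced six rows
  p1 <- rec$participant == "p01"
  expect_equal(sum(d$X[p1, "awe_contrast"]), 0)
  expect_equal(sum(d$X[p1, "amusement_contrast"]), 0)
  # covariates are centered
  expect_equal(mean(d$X[, "temperature"]), 0, tolerance = 1e-12)

  d_ord <- build_design(rec, "y", variant = "order")
  expect_setequal(unique(d_ord$X[, "order"]), c(-0.5, 0.5))
  one_awe <- rec$participant == "p01" & rec$condition == "awe"
  expect_setequal(d_ord$X[one_awe, "order"], c(-0.5, 0.5))

  d_dem <- build_design(rec, "y", variant = "demographic")
  expect_equal(mean(d_dem$X[, "age"]), 0, tolerance = 1e-12)
  expect_setequal(unique(d_dem$X[, "gender"]), c(-0.5, 0.5))
  expect_true("awe_contrast:age" %in% colnames(d_dem$X))

  rec$amusement <- rnorm(nrow(rec), 3, 1)
  rec$fear <- 1.5
  # a constant fear column is collinear with the intercept after centering
  expect_error(build_design(rec, "y", variant = "control"), "singular")
  rec$fear <- rnorm(nrow(rec), 2, 0.5)
  expect_true("fear_rating" %in%
                colnames(build_design(rec, "y", variant = "control")$X))

  bad <- rec; bad$condition[1] <- "panic"
  expect_error(build_design(bad, "y"), "unknown condition")
})

test_that("hierarchical fit recovers the balanced-design estimands", {
  rec <- make_balanced_records(20, seed = 9, noise_sd = 0.1)
  # single-contrast model: coefficient is the awe-versus-others difference
  fit_a <- fit_hier(build_design(rec, "y", covariates = character(0),
                                 contrasts = "awe"), seed = 4)
  expect_equal(unname(coef(fit_a)["awe_contrast"]), 2.5, tolerance = 0.05)

  # both contrasts: coefficient is awe - neutral; agrees with lme4
  des <- build_design(rec, "y", covariates = character(0))
  fit_b <- fit_hier(des, seed = 4)
  library(lme4)
  rec$awe_c <- ifelse(rec$condition == "awe", 2 / 3, -1 / 3)
  rec$amu_c <- ifelse(rec$condition == "amusement", 2 / 3, -1 / 3)
  fm <- lme4::lmer(y ~ awe_c + amu_c + (1 | participant), data = rec)
  bf <- lme4::fixef(fm)
  expect_equal(unname(coef(fit_b)["awe_contrast"]),
               unname(bf["awe_c"]), tolerance = 0.02)
  expect_equal(unname(coef(fit_b)["amusement_contrast"]),
               unname(bf["amu_c"]), tolerance = 0.05)
  expect_true(fit_b$converged)

  # constant outcome: contrast posteriors center at zero
  rec0 <- rec; rec0$y <- 3
  f0 <- fit_hier(build_design(rec0, "y", covariates = character(0)),
                 chains = 2, iter = 800, warmup = 400, seed = 5)
  expect_lt(abs(coef(f0)["awe_contrast"]), 0.01)
  expect_false(f0$table$significant[f0$table$term == "awe_contrast"])
})

test_that("posteriors are location and scale equivariant", {
  rec <- make_balanced_records(12, seed = 13)
  des <- build_design(rec, "y", covariates = character(0))
  f1 <- fit_hier(des, chains = 2, iter = 1000, warmup = 500, seed = 6)

  rec_c <- rec; rec_c$y <- rec$y + 100
  f2 <- fit_hier(build_design(rec_c, "y", covariates = character(0)),
                 chains = 2, iter = 1000, warmup = 500, seed = 6)
  expect_equal(unname(coef(f2)["(Intercept)"] - coef(f1)["(Intercept)"]),
               100, tolerance = 0.5)
  expect_equal(unname(coef(f2)["awe_contrast"]),
               unname(coef(f1)["awe_contrast"]), tolerance = 0.05)

  rec_k <- rec; rec_k$y <- rec$y * 3
  f3 <- fit_hier(build_design(rec_k, "y", covariates = character(0)),
                 chains = 2, iter = 1000, warmup = 500, seed = 6)
  expect_equal(unname(coef(f3)["awe_contrast"] / coef(f1)["awe_contrast"]),
               3, tolerance = 0.05)
  expect_equal(mean(f3$draws$sigma) / mean(f1$draws$sigma), 3,
               tolerance = 0.1)
})

test_that("chained-equations imputation: identity, MCAR recovery, m", {
  rec <- make_balanced_records(15, seed = 17)
  rec$x <- rec$y + rnorm(nrow(rec), 0, 0.3)

  # nothing missing: all m tables equal the input
  imp0 <- impute_missing(rec, vars = c("y", "x"), m = 3, seed = 1)
  expect_length(imp0, 3)
  for (d in imp0) expect_equal(d$y, rec$y)

  # 20% MCAR on x: pooled slope within 1 pooled SE of complete-data slope
  set.seed(23)
  miss <- sample(nrow(rec), round(0.2 * nrow(rec)))
  rec_m <- rec; rec_m$x[miss] <- NA
  imp <- impute_missing(rec_m, vars = c("y", "x", "temperature"),
                        m = 10, seed = 2)
  expect_length(imp, 10)
  for (d in imp) expect_false(anyNA(d$x))
  # imputed tables agree with the data where observed
  expect_equal(imp[[1]]$x[-miss], rec$x[-miss])
  slope_full <- coef(lm(y ~ x, rec))["x"]
  slopes <- vapply(imp, function(d) coef(lm(y ~ x, d))["x"], numeric(1))
  se_full <- summary(lm(y ~ x, rec))$coefficients["x", "Std. Error"]
  expect_lt(abs(mean(slopes) - slope_full), 2 * se_full)

  expect_error(impute_missing(transform(rec, z = NA_real_),
                              vars = c("y", "z"), m = 2),
               "no observed values")
})

test_that("pooled regression stacks draws across imputations", {
  set.seed(31)
  n <- 60
  d <- data.frame(x = rnorm(n), participant = sprintf("p%d", 1:n))
  d$y <- 1 + 0.2 * d$x + rnorm(n, 0, 0.1)

  # m = 1 with nothing missing reduces to a single fit
  one <- fit_regression_pooled(list(d), "y", "x", chains = 2, iter = 600,
                               warmup = 300, seed = 3)
  expect_equal(ncol(one$draws$x), 2)
  ls_slope <- unname(coef(lm(y ~ x, d))["x"])
  expect_equal(unname(coef(one)["x"]), ls_slope, tolerance = 0.02)

  dm <- d; dm$y[sample(n, 12)] <- NA
  imp <- impute_missing(dm, vars = c("y", "x"), m = 5, seed = 4)
  pooled <- fit_regression_pooled(imp, "y", "x", chains = 2, iter = 600,
                                  warmup = 300, seed = 5)
  # stacked draw count = m x chains x kept
  expect_equal(ncol(pooled$draws$x), 5 * 2)
  expect_equal(nrow(pooled$draws$x), 300)
  tab <- pooled$table
  xr <- tab[tab$term == "x", ]
  # pooled estimate stays close to the complete-data estimate
  se_full <- summary(lm(y ~ x, d))$coefficients["x", "Std. Error"]
  expect_lt(abs(xr$eap - ls_slope), 2 * se_full)
  expect_true(xr$lower < ls_slope && ls_slope < xr$upper)
})

test_that("results tables have the study layout and handle empty input", {
  expect_equal(nrow(summarize_fits(list())), 0)

  # constructed draws: EAP and equal-tailed CI from empirical quantiles
  draws <- list(`(Intercept)` = matrix(c(1, 2, 3, 4), 4, 1),
                awe_contrast = matrix(c(1, 2, 3, 4), 4, 1))
  f <- awedyn:::build_contrast_fit(draws,
                                   list(terms = names(draws),
                                        outcome = "demo",
                                        variant = "simple"),
                                   config = list())
  row <- f$table[f$table$term == "awe_contrast", ]
  expect_equal(row$eap, 2.5)
  expect_equal(row$lower, unname(quantile(1:4, 0.025)))
  expect_equal(row$upper, unname(quantile(1:4, 0.975)))
  expect_true(row$significant)  # CI [1.07, 3.93] excludes 0

  tab <- summarize_fits(list(f))
  expect_setequal(names(tab),
                  c("outcome", "term", "eap", "lower", "upper", "rhat",
                    "ess_bulk", "ess_tail", "significant"))
  expect_equal(tab$term, "awe_contrast")

  # a CI spanning zero is not significant
  d2 <- list(x = matrix(c(-0.04, 0.1, 0.25), 3, 1))
  f2 <- awedyn:::build_contrast_fit(d2, list(terms = "x", outcome = "o",
                                             variant = "simple"),
                                    config = list())
  expect_false(f2$table$significant)
})
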