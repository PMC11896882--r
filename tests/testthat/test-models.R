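test_that("OLS fit: exact fits, degenerate designs, and CI coverage", {
  x <- seq_len(30)
  f <- suppressWarnings(ols_fit(2 * x + 1, data.frame(x = x))) # exact fit
  expect_equal(f$r_squared, 1)
  expect_lt(max(abs(residuals(f$lm))), 1e-10)
  # constant-only design collapses to the intercept model
  f0 <- ols_fit(rnorm(30), data.frame(z = rep(1, 30)))
  expect_equal(f0$r_squared, 0)
  expect_error(ols_fit(rnorm(10), data.frame(a = 1:10, b = 2 * (1:10))),
               "rank-deficient")
  # 95% Wald CI covers the true slope at close to nominal rate
  set.seed(101)
  covered <- vapply(seq_len(500), function(k) {
    xx <- rnorm(200)
    fit <- ols_fit(2 * xx + rnorm(200, 0, 0.1), data.frame(x = xx))
    co <- fit$coefficients[fit$coefficients$term == "x", ]
    co$lower <= 2 && 2 <= co$upper
  }, TRUE)
  expect_gte(mean(covered), 0.93)
})

test_that("stepwise AIC selection keeps strong predictors, beats the
           bracketing models, and matches the exhaustive-subset oracle", {
  set.seed(102)
  n <- 144
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- paste0("v", 1:6)
  kept <- vapply(seq_len(100), function(k) {
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- paste0("v", 1:6)
    y <- 1 * X$v1 + rnorm(n)
    "v1" %in% stepwise_select(y, X)$predictors
  }, TRUE)
  expect_gte(mean(kept), 0.95)
  # algorithm guarantee: selected AIC <= full and intercept-only AIC
  y <- rnorm(n)
  sel <- stepwise_select(y, X)
  expect_lte(sel$aic, aic_gauss(lm(y ~ ., data = X)) + 1e-8)
  expect_lte(sel$aic, aic_gauss(lm(y ~ 1)) + 1e-8)
  # greedy vs brute force over all 2^5 subsets
  set.seed(103)
  subsets <- lapply(0:31, function(m) which(bitwAnd(m, 2^(0:4)) > 0))
  match_oracle <- vapply(seq_len(50), function(k) {
    Xs <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
    names(Xs) <- paste0("v", 1:5)
    ys <- 0.8 * Xs$v1 - 0.5 * Xs$v3 + rnorm(40)
    best <- min(vapply(subsets, function(s) {
      if (length(s)) aic_gauss(lm(ys ~ ., data = Xs[, s, drop = FALSE]))
      else aic_gauss(lm(ys ~ 1))
    }, 0))
    abs(stepwise_select(ys, Xs)$aic - best) < 1e-8
  }, TRUE)
  expect_gte(mean(match_oracle), 0.9)
})

test_that("REML random-intercept check: null, power and recovery", {
  set.seed(104)
  g <- rep(1:4, each = 36)
  X <- data.frame(x = rnorm(144))
  # zero between-group variance: negligible group variance, insignificant LR
  y0 <- rnorm(144)
  t0 <- lr_test_random_effect(y0, X, g)
  expect_gte(t0$lr, 0)
  expect_gt(t0$p_value, 0.1)
  expect_lt(t0$var_group, 0.3 * t0$var_resid)
  # group sd twice the residual sd: detected at alpha = 0.1 almost always
  hits <- vapply(seq_len(50), function(k) {
    y <- rnorm(144) + rep(rnorm(4, 0, 2), each = 36)
    lr_test_random_effect(y, X, g)$p_value < 0.1
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # variance components recovered at n = 1000, 20 groups (replicate means,
  # since a single 20-group draw estimates the group variance with ~30% sd)
  set.seed(105)
  g2 <- rep(1:20, each = 50)
  est <- vapply(seq_len(40), function(k) {
    y2 <- rep(rnorm(20, 0, 1), each = 50) + rnorm(1000)
    m <- reml_random_intercept(y2, data.frame(x = rnorm(1000)), g2)
    c(m$var_group, m$var_resid)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 1), 0.2)
  expect_lt(abs(mean(est[2, ]) - 1), 0.2)
  expect_error(reml_random_intercept(rnorm(10), data.frame(x = rnorm(10)),
                                     rep(1, 10)), "2 groups")
})

test_that("stepwise selection on the generated community recovers the
           planted structure signal with the right signs", {
  cfg <- small_config(seed = 106, n_plots = 4,
                      beta_structure = c(meanTCH = -0.5, GHFC = -0.3))
  sim <- simulate_community(cfg)
  st <- quadrat_liana_structure(sim$lianas, sim$quadrats)
  z <- as.data.frame(standardize_env(sim$env))
  fit <- stepwise_select(st$N_L, z, response = "N_L")
  expect_true(all(c("meanTCH", "GHFC") %in% fit$predictors))
  co <- fit$coefficients
  expect_lt(co$estimate[co$term == "meanTCH"], 0)
  expect_lt(co$estimate[co$term == "GHFC"], 0)
})
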