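test_that("preprocess_epoch removes mean and linear trend", {
  set.seed(31)
  T <- 250
  t_ax <- seq_len(T)
  # already centered and trend-free input is (numerically) unchanged
  x0 <- matrix(rnorm(2 * T), 2, T)
  x0 <- preprocess_epoch(x0)
  expect_equal(preprocess_epoch(x0), x0, tolerance = 1e-10,
               ignore_attr = TRUE)

  # a pure linear ramp vanishes
  ramp <- rbind(3 + 0.01 * t_ax, rnorm(T))
  out <- preprocess_epoch(ramp)
  expect_lt(max(abs(out[1, ])), 1e-10)

  # sinusoid + offset + drift: equals the independent least-squares
  # detrend oracle and stays essentially the pure tone
  s <- sin(2 * pi * 6 * t_ax / 250)
  y <- preprocess_epoch(rbind(s + 0.5 + 0.02 * t_ax, rnorm(T)))
  oracle <- unname(residuals(lm(I(s + 0.5 + 0.02 * t_ax) ~ t_ax)))
  expect_equal(unname(y[1, ]), oracle, tolerance = 1e-10)
  expect_gt(cor(y[1, ], s), 0.99)

  # constant channel comes back as zeros, with a warning
  expect_warning(z <- preprocess_epoch(rbind(rep(2, T), rnorm(T))),
                 "constant")
  expect_true(all(z[1, ] == 0))
  expect_equal(attr(z, "constant_channels"), 1L)
})

test_that("fit_mvar recovers coefficients and satisfies OLS identities", {
  spec <- bivariate_coupled_spec(0.4)
  x <- preprocess_epoch(simulate_var(spec, 1e5, seed = 41))
  fit <- fit_mvar(x, 1)
  expect_equal(fit$coeffs[[1]], spec$coeffs[[1]], tolerance = 0.01,
               ignore_attr = TRUE)

  # white noise: all coefficients within 3 standard errors of zero
  wn <- preprocess_epoch(matrix(rnorm(3 * 5000), 3, 5000))
  f0 <- fit_mvar(wn, 1)
  se <- sqrt(diag(f0$noise_cov)) %o% (1 / apply(wn, 1, sd)) / sqrt(5000)
  expect_true(all(abs(f0$coeffs[[1]]) < 3.5 * se))

  # residuals orthogonal to lagged regressors (normal equations)
  W <- gcflow:::var_embed(t(x), 1)
  Z <- W[, 1:2]
  expect_lt(max(abs(crossprod(Z, t(fit$residuals)))) / fit$n_obs, 1e-8)

  # noise_cov is the sample covariance of the stored residuals
  expect_equal(fit$noise_cov, cov(t(fit$residuals)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # round trip: simulating from the fit reproduces the channel covariance
  refit_spec <- var_spec(fit$coeffs, noise_cov = fit$noise_cov,
                         labels = fit$labels)
  G0 <- oracle_var_autocov(refit_spec$coeffs, refit_spec$noise_cov, 0L)
  expect_equal(cov(t(x)), G0, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("ensemble fitting pools trials without crossing boundaries", {
  spec <- hub_var_spec("PCC-hub")
  trials <- lapply(1:80, function(k) {
    preprocess_epoch(simulate_var(spec, 250, seed = 400 + k))
  })
  fit <- fit_mvar(trials, 2)
  expect_equal(fit$n_obs, 80 * 248)
  expect_equal(fit$coeffs[[1]], spec$coeffs[[1]], tolerance = 0.05,
               ignore_attr = TRUE)
  expect_error(fit_mvar(trials[[1]][, 1:10, drop = FALSE], 4),
               "too few")
})

test_that("BIC selects the true order and ties break low", {
  spec <- hub_var_spec("PCC-hub")   # genuine VAR(2)
  hits <- 0L
  for (s in 1:20) {
    x <- preprocess_epoch(simulate_var(spec, 2500, seed = 500 + s))
    sel <- select_order_bic(x, 8)
    if (sel$order == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)

  # white noise: penalty dominates, order 1 or a flagged flat profile
  wn <- preprocess_epoch(matrix(rnorm(4 * 3000), 4, 3000))
  sel0 <- select_order_bic(wn, 5)
  expect_true(sel0$order == 1L || sel0$flat)

  # BIC at the true order beats true order + 3
  x <- preprocess_epoch(simulate_var(spec, 2500, seed = 601))
  sel2 <- select_order_bic(x, 6)
  expect_lt(sel2$bic[2], sel2$bic[5])

  # boundary legality: tiny sample still returns, with a warning
  tiny <- preprocess_epoch(matrix(rnorm(2 * 12), 2, 12))
  expect_warning(sel3 <- select_order_bic(tiny, 3), "degenerate")
  expect_true(sel3$order %in% 1:3)
})

test_that("validation diagnostics behave on well- and mis-specified fits", {
  spec <- hub_var_spec("PCC-hub")
  ok <- 0L
  for (s in 1:10) {
    x <- preprocess_epoch(simulate_var(spec, 2000, seed = 700 + s))
    fit <- fit_mvar(x, 2)
    val <- validate_model(fit, x)
    expect_true(val$stable)
    expect_gt(val$consistency_pct, 80)
    if (val$whiteness_overall > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 7L)   # correctly specified: whiteness rarely rejected

  # underfit (p = 1 on VAR(2) data) is flagged by the whiteness test
  rejects <- 0L
  for (s in 1:10) {
    x <- preprocess_epoch(simulate_var(spec, 2000, seed = 800 + s))
    fit1 <- fit_mvar(x, 1)
    if (validate_model(fit1, x)$whiteness_overall < 0.05) {
      rejects <- rejects + 1L
    }
  }
  expect_gte(rejects, 6L)

  # force an explosive coefficient set: stability check must fail
  x <- preprocess_epoch(simulate_var(spec, 500, seed = 900))
  fit <- fit_mvar(x, 2)
  fit$coeffs[[1]] <- diag(1.05, 6)
  fit$coeffs[[2]] <- matrix(0, 6, 6)
  val <- validate_model(fit, x)
  expect_false(val$stable)
  expect_gt(val$spectral_radius, 1)
})
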