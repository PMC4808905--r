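test_that("simulate_var reproduces known second moments", {
  # white noise: identity covariance
  wn <- var_spec(list(matrix(0, 2, 2)), labels = c("a", "b"))
  x <- simulate_var(wn, 1e5, seed = 1)
  expect_equal(unname(apply(x, 1, var)), c(1, 1), tolerance = 0.03)
  expect_lt(abs(cor(x[1, ], x[2, ])), 0.02)

  # univariate AR(1), a = 0.5: stationary variance 1/(1 - 0.25)
  ar1 <- var_spec(list(matrix(0.5, 1, 1)), labels = "u")
  y <- simulate_var(ar1, 1e5, seed = 2)
  expect_equal(var(as.vector(y)), 1 / 0.75, tolerance = 0.05)

  # bivariate VAR(1): lag-1 cross-covariance against the Lyapunov oracle
  spec <- bivariate_coupled_spec(0.4)
  z <- simulate_var(spec, 1e5, seed = 3)
  G1 <- oracle_var_autocov(spec$coeffs, spec$noise_cov, 1L)
  T <- ncol(z)
  emp_G1 <- tcrossprod(z[, 2:T] - rowMeans(z), z[, 1:(T - 1)] - rowMeans(z)) / (T - 1)
  expect_equal(emp_G1, G1, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("simulate_var enforces stationarity and determinism", {
  bad <- var_spec(list(matrix(1.05, 1, 1)), labels = "u")
  expect_error(simulate_var(bad, 100, seed = 1), "spectral radius")
  spec <- bivariate_coupled_spec()
  expect_identical(simulate_var(spec, 500, seed = 7),
                   simulate_var(spec, 500, seed = 7))
  expect_false(identical(simulate_var(spec, 500, seed = 7),
                         simulate_var(spec, 500, seed = 8)))
})

test_that("shipped hub templates are stationary and wired as documented", {
  for (tpl in c("PCC-hub", "MCC-hub", "null")) {
    spec <- hub_var_spec(tpl)
    expect_lt(spectral_radius(spec), 1)
    adj <- attr(spec, "adjacency")
    od <- colSums(adj)
    if (tpl == "PCC-hub") {
      expect_equal(names(which.max(od)), "PCC")
      expect_equal(sum(adj), 9)
    }
    if (tpl == "MCC-hub") {
      expect_equal(unname(od["MCC"]), 5)
      expect_equal(sum(adj), 10)
    }
    if (tpl == "null") expect_equal(sum(adj), 0)
    # long-run covariance agrees with the Lyapunov solution
    x <- simulate_var(spec, 2e4, seed = 11)
    G0 <- oracle_var_autocov(spec$coeffs, spec$noise_cov, 0L)
    expect_equal(cov(t(x)), G0, tolerance = 0.1, ignore_attr = TRUE)
  }
})

test_that("build_scenario draws regimes, RTs and bookkeeping correctly", {
  # degenerate mixture: every trial carries the single regime
  scn1 <- scenario(
    regime_probs = list("K+" = c("PCC-hub" = 1)),
    n_trials = 50, n_subjects = 1, seed = 4
  )
  ep1 <- build_scenario(scn1)
  expect_true(all(ep1$meta$regime_truth == "PCC-hub"))
  expect_equal(length(ep1$trials), 50)

  # mixture fractions concentrate near the planted probabilities
  scn2 <- scenario(
    regime_probs = list("K+" = c("MCC-hub" = 0.3, "PCC-hub" = 0.3,
                                 "null" = 0.4)),
    n_trials = 2000, n_subjects = 1, seed = 5
  )
  ep2 <- build_scenario(scn2)
  frac <- table(ep2$meta$regime_truth) / 2000
  expect_equal(unname(frac["MCC-hub"]), 0.3, tolerance = 0.1)
  expect_equal(unname(frac["PCC-hub"]), 0.3, tolerance = 0.1)
  expect_equal(unname(frac["null"]), 0.4, tolerance = 0.075)

  # planted RT medians are ordered as specified
  scn3 <- scenario(
    regime_probs = list("K+" = c("MCC-hub" = 0.5, "PCC-hub" = 0.5)),
    n_trials = 1000, n_subjects = 1, seed = 6
  )
  ep3 <- build_scenario(scn3)
  med <- tapply(ep3$meta$rt, ep3$meta$regime_truth, median)
  expect_lt(med["MCC-hub"], med["PCC-hub"])
  expect_equal(unname(med["MCC-hub"]), 1.0, tolerance = 0.05)
  expect_equal(unname(med["PCC-hub"]), 1.3, tolerance = 0.07)
})

test_that("scenario generation is seed-deterministic and re-simulable", {
  scn <- scenario(n_trials = 5, n_subjects = 2, seed = 9)
  a <- build_scenario(scn)
  b <- build_scenario(scn)
  expect_identical(a, b)

  # planted-truth bookkeeping: re-simulating a trial from its recorded
  # seed reproduces its data exactly
  k <- 7L
  tr <- gcflow:::simulate_trial(scn, a$meta$regime_truth[k],
                                a$meta$trial_seed[k])
  expect_identical(tr$data, a$trials[[k]])
  expect_identical(tr$rt, a$meta$rt[k])
})

test_that("scenario validation rejects malformed inputs", {
  expect_error(
    scenario(regime_probs = list("K+" = c("no-such-regime" = 1))),
    "unknown regime"
  )
  expect_error(
    scenario(regime_probs = list("K+" = c("MCC-hub" = 0.6, "null" = 0.6))),
    "sum to 1"
  )
})

test_that("add_oscillation injects a narrowband component with the right power", {
  ep <- white_epochs(40, n_channels = 3, T = 250, seed = 21,
                     labels = c("ACC", "MCC", "PCC"))
  # amplitude 0 is the identity
  ep0 <- add_oscillation(ep, "MCC", freq = 6, amplitude = 0, seed = 1)
  expect_equal(ep0$trials, ep$trials)

  # sinusoid power a^2/2 on average
  a <- 2
  ep2 <- add_oscillation(ep, "MCC", freq = 6, amplitude = a, seed = 2)
  dv <- mean(vapply(seq_along(ep$trials), function(k) {
    var(ep2$trials[[k]][2, ]) - var(ep$trials[[k]][2, ])
  }, 0))
  expect_equal(dv, a^2 / 2, tolerance = 0.2)

  # spectral peak lands in the bin nearest 6 Hz on the right channel only
  psd_mean <- function(eps, ch) {
    rowMeans(vapply(eps$trials,
                    function(m) welch_log_psd(m[ch, ], fs = 250)$psd,
                    numeric(31)))
  }
  f <- welch_log_psd(ep2$trials[[1]][2, ], fs = 250)$freq
  peak_bin <- which.max(psd_mean(ep2, 2))
  expect_equal(f[peak_bin], f[which.min(abs(f - 6))])
  flat <- psd_mean(ep2, 1)
  expect_lt(max(flat) / min(flat), 10)   # untouched channel stays broadband

  expect_error(add_oscillation(ep, "MCC", freq = 200, amplitude = 1),
               "fs/2")
})
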