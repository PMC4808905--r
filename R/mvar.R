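#' Detrend and center a single epoch
#'
#' Removes, per channel, the least-squares linear trend and the temporal
#' mean, the standard guard against slow drift before autoregressive
#' fitting. A constant channel is returned as all zeros and flagged in the
#' `"constant_channels"` attribute (with a warning).
#'
#' @param x numeric `channels x samples` matrix (at least 2 samples).
#' @return matrix of the same shape, each channel zero-mean and trend-free.
#' @export
preprocess_epoch <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  T <- ncol(x)
  tc <- seq_len(T) - (T + 1) / 2               # centered time axis
  stt <- sum(tc^2)
  mu <- rowMeans(x)
  slope <- (x %*% tc) / stt
  out <- x - mu - tcrossprod(as.vector(slope), tc)
  const <- apply(x, 1L, function(r) max(r) == min(r))
  if (any(const)) {
    out[const, ] <- 0
    warning("constant channel(s) set to zero: ",
            paste(which(const), collapse = ", "))
  }
  attr(out, "constant_channels") <- which(const)
  out
}

# --- lagged-regression plumbing ------------------------------------------
#
# All fitting and Granger-causality computation runs off one Gram matrix
# G = crossprod(W) with W = [lag-1 block | ... | lag-p block | current],
# accumulated over trials so that no lagged regressor ever crosses a trial
# boundary (ensemble fitting of short epochs). Column j of lag block k is
# channel j at lag k; the last n columns are the unlagged targets.

as_trial_list <- function(x) {
  if (inherits(x, "epoch_set")) return(x$trials)
  if (is.matrix(x)) return(list(x))
  stopifnot(is.list(x), length(x) >= 1L)
  x
}

var_embed <- function(xt, p) {              # xt: samples x channels
  T <- nrow(xt)
  blocks <- vector("list", p + 1L)
  for (k in seq_len(p)) blocks[[k]] <- xt[(p + 1L - k):(T - k), , drop = FALSE]
  blocks[[p + 1L]] <- xt[(p + 1L):T, , drop = FALSE]
  do.call(cbind, blocks)
}

var_gram <- function(trials, p) {
  n <- nrow(trials[[1L]])
  m <- n * (p + 1L)
  G <- matrix(0, m, m)
  N <- 0L
  for (x in trials) {
    if (ncol(x) <= p) stop("trial shorter than the model order")
    W <- var_embed(t(x), p)
    G <- G + crossprod(W)
    N <- N + nrow(W)
  }
  list(G = G, N = N, n = n, p = p)
}

# OLS solve from the Gram matrix. Returns coefficient matrix B
# ((n*p) x n, regressors -> targets) and residual sums of squares/cross
# products. `ridge = 0`; a failed Cholesky signals rank deficiency.
gram_ols <- function(gram) {
  n <- gram$n; p <- gram$p
  m <- n * p
  zi <- seq_len(m); yi <- m + seq_len(n)
  Szz <- gram$G[zi, zi, drop = FALSE]
  Szy <- gram$G[zi, yi, drop = FALSE]
  Syy <- gram$G[yi, yi, drop = FALSE]
  R <- tryCatch(chol(Szz), error = function(e) NULL)
  if (is.null(R)) {
    bad <- which(abs(diag(suppressWarnings(
      chol(Szz, pivot = TRUE)))) < sqrt(.Machine$double.eps) * sqrt(max(diag(Szz))))
    ch <- sort(unique((attr(suppressWarnings(chol(Szz, pivot = TRUE)),
                            "pivot")[bad] - 1L) %% n + 1L))
    stop("rank-deficient regressor matrix (collinear lagged channels: ",
         paste(ch, collapse = ", "), ")")
  }
  B <- backsolve(R, forwardsolve(t(R), Szy))
  RSS <- Syy - crossprod(Szy, B)
  list(B = B, RSS = RSS, N = gram$N)
}

#' Fit a multivariate autoregressive model by ordinary least squares
#'
#' Estimates the VAR(p) coefficient matrices minimizing the summed squared
#' one-step prediction error. Input should be detrended/centered (see
#' [preprocess_epoch()]); no intercept is fitted. A list of trials (or an
#' [epoch_set()]) is fitted as an ensemble: lagged regressor blocks are
#' built per trial and pooled, so no lag crosses a trial boundary.
#'
#' @param x `channels x samples` matrix, list of such matrices, or
#'   [epoch_set()].
#' @param p model order (number of lags).
#' @param labels optional channel names (taken from the data when present).
#' @return An object of class `var_model`: `order`, `coeffs` (list of p
#'   matrices, `[i, j]` = effect of channel j on channel i), `noise_cov`
#'   (unbiased sample covariance of the residuals), `residuals`
#'   (`channels x N` prediction errors), `n_obs`, `labels`.
#' @export
fit_mvar <- function(x, p, labels = NULL) {
  trials <- as_trial_list(x)
  stopifnot(is_count(p))
  n <- nrow(trials[[1L]])
  N_tot <- sum(vapply(trials, ncol, 0L)) - p * length(trials)
  if (N_tot <= n * p + 1L) {
    stop("too few effective observations (", N_tot, ") for n*p+1 = ",
         n * p + 1L)
  }
  if (is.null(labels)) labels <- rownames(trials[[1L]]) %||% paste0("ch", 1:n)
  gram <- var_gram(trials, p)
  fit <- gram_ols(gram)
  coeffs <- lapply(seq_len(p), function(k) {
    A <- t(fit$B[(k - 1L) * n + seq_len(n), , drop = FALSE])
    dimnames(A) <- list(labels, labels)
    A
  })
  resid <- do.call(cbind, lapply(trials, function(xm) {
    W <- var_embed(t(xm), p)
    m <- n * p
    t(W[, m + seq_len(n), drop = FALSE] -
        W[, seq_len(m), drop = FALSE] %*% fit$B)
  }))
  rownames(resid) <- labels
  noise_cov <- tcrossprod(resid) / (gram$N - 1L)
  structure(
    list(order = as.integer(p), coeffs = coeffs, noise_cov = noise_cov,
         residuals = resid, n_obs = gram$N, n_channels = n,
         labels = labels, gram = gram,
         trial_lengths = vapply(trials, ncol, 0L) - p),
    class = "var_model"
  )
}

#' @export
print.var_model <- function(x, ...) {
  cat("VAR(", x$order, ") fit: ", x$n_channels, " channels, ", x$n_obs,
      " effective observations\n", sep = "")
  cat("  residual variances:",
      paste(format(diag(x$noise_cov), digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Select the model order by the Bayesian information criterion
#'
#' Fits orders 1..`p_max` on a common effective sample (all regressions
#' start at `p_max + 1` within each trial, so criteria are comparable
#' across orders) and returns the BIC minimizer
#' \deqn{BIC(p) = \ln\det\hat\Sigma_p + \frac{\ln N}{N}\, p\, n^2,}
#' with \eqn{\hat\Sigma_p} the maximum-likelihood residual covariance and
#' `N` the pooled effective observation count. Ties break toward the
#' smaller order; orders with a singular residual covariance are marked
#' invalid and excluded.
#'
#' @inheritParams fit_mvar
#' @param p_max largest order considered.
#' @return list with `order` (selected p), `bic` (per-order values, `NA`
#'   where invalid), `n_obs`, and `flat` (TRUE when the BIC range across
#'   valid orders is < 0.01, i.e. the profile is near-flat and the penalty
#'   dominates).
#' @export
select_order_bic <- function(x, p_max) {
  trials <- as_trial_list(x)
  stopifnot(is_count(p_max))
  n <- nrow(trials[[1L]])
  T_min <- min(vapply(trials, ncol, 0L))
  if (T_min <= p_max) stop("shortest trial (", T_min, ") must exceed p_max")
  gram <- var_gram(trials, p_max)
  N <- gram$N
  if (N <= p_max * n + 1L) {
    stop("too few effective observations for p_max = ", p_max)
  }
  if (N <= p_max * n + n + 5L) {
    warning("sample barely exceeds the regressor count; order selection ",
            "is degenerate")
  }
  m_full <- n * p_max
  yi <- m_full + seq_len(n)
  bic <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    zi <- seq_len(n * p)
    Gp <- gram$G[c(zi, yi), c(zi, yi), drop = FALSE]
    fit <- tryCatch(gram_ols(list(G = Gp, N = N, n = n, p = p)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    Sig <- fit$RSS / N
    ld <- tryCatch(2 * sum(log(diag(chol(Sig)))), error = function(e) NA_real_)
    if (is.na(ld)) next
    bic[p] <- ld + (log(N) / N) * p * n^2
  }
  if (all(is.na(bic))) stop("no valid order in 1..p_max")
  sel <- which(bic == min(bic, na.rm = TRUE))[1L]   # ties -> smaller p
  list(order = as.integer(sel), bic = bic, n_obs = N,
       flat = diff(range(bic, na.rm = TRUE)) < 0.01)
}

#' Validate a fitted MVAR model
#'
#' Three standard checks: (1) whiteness of the residuals — a Ljung–Box
#' portmanteau test per channel (lags `min(20, floor(N/5))`) plus a
#' Bonferroni-combined overall p-value; for ensemble fits the test runs
#' per trial and is Fisher-combined across trials within each channel
#' (a portmanteau pooled over tens of thousands of concatenated samples
#' would otherwise flag the O(1/T) autocorrelation that per-trial
#' detrending necessarily leaves); (2) percentage consistency — the
#' model is simulated once at matched length (fixed internal seed) and the
#' pairwise covariance structure of the simulation is compared with the
#' observed one, `100 * (1 - ||C_sim - C_obs|| / ||C_obs||)`; (3) stability
#' — the companion-matrix spectral radius must be below 1.
#'
#' @param model a [fit_mvar()] result.
#' @param x the data it was fitted on (matrix, list of trials, or
#'   [epoch_set()]).
#' @return An object of class `validation_report`: `whiteness_pvalue`
#'   (per-channel vector plus `overall` attribute), `whiteness_overall`,
#'   `consistency_pct`, `stable`, `spectral_radius`.
#' @export
validate_model <- function(model, x) {
  stopifnot(inherits(model, "var_model"))
  trials <- as_trial_list(x)
  lens <- model$trial_lengths %||% ncol(model$residuals)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  wp <- apply(model$residuals, 1L, function(r) {
    ps <- vapply(seq_along(lens), function(k) {
      seg <- r[starts[k]:ends[k]]
      lag_max <- max(2L, min(20L, floor(length(seg) / 5)))
      stats::Box.test(seg, lag = lag_max, type = "Ljung-Box")$p.value
    }, 0)
    if (length(ps) == 1L) return(ps)
    # Fisher combination across trials
    stats::pchisq(-2 * sum(log(pmax(ps, 1e-300))), 2 * length(ps),
                  lower.tail = FALSE)
  })
  names(wp) <- model$labels
  overall <- min(1, length(wp) * min(wp))

  obs <- do.call(cbind, trials)
  C_obs <- stats::cov(t(obs))
  spec <- var_spec(model$coeffs, noise_cov = model$noise_cov,
                   labels = model$labels)
  sr <- spectral_radius(spec)
  if (sr < 1) {
    sim <- simulate_var(spec, n_samples = ncol(obs), seed = 8675309L)
    C_sim <- stats::cov(t(sim))
    consistency <- 100 * (1 - norm(C_sim - C_obs, "F") / norm(C_obs, "F"))
  } else {
    consistency <- NA_real_      # unstable model has no stationary moments
  }
  structure(
    list(whiteness_pvalue = wp, whiteness_overall = overall,
         consistency_pct = consistency, stable = sr < 1,
         spectral_radius = sr),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("MVAR validation:\n")
  cat("  whiteness (Ljung-Box) overall p:",
      format(x$whiteness_overall, digits = 3), "\n")
  cat("  consistency:", format(x$consistency_pct, digits = 4), "%\n")
  cat("  stable:", x$stable,
      "(spectral radius", format(x$spectral_radius, digits = 4), ")\n")
  invisible(x)
}
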