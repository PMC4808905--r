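# Independent oracles used to check the implementation. Everything here is
# deliberately brute-force / closed-form and shares no code with R/.

# Stationary autocovariance Gamma(lag) of a VAR(p) via the companion-form
# discrete Lyapunov equation solved by the vec trick.
oracle_var_autocov <- function(coeffs, noise_cov, lag = 0L) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  n <- nrow(coeffs[[1L]])
  p <- length(coeffs)
  np <- n * p
  Ac <- matrix(0, np, np)
  for (k in seq_len(p)) Ac[1:n, (k - 1L) * n + 1:n] <- coeffs[[k]]
  if (p > 1L) Ac[(n + 1L):np, 1:(n * (p - 1L))] <- diag(n * (p - 1L))
  Qc <- matrix(0, np, np)
  Qc[1:n, 1:n] <- noise_cov
  Gc <- matrix(solve(diag(np^2) - kronecker(Ac, Ac), as.vector(Qc)), np, np)
  for (l in seq_len(max(0L, lag))) Gc <- Ac %*% Gc
  Gc[1:n, 1:n]
}

# Analytic Granger magnitude F(source -> target) for a bivariate VAR(1)
# under the pipeline's convention: restricted model = AR(1) fitted to the
# target alone, variances taken at the population level.
oracle_gc_bivariate_var1 <- function(A, noise_cov = diag(2), source = 2L,
                                     target = 1L) {
  G0 <- oracle_var_autocov(A, noise_cov, 0L)
  G1 <- oracle_var_autocov(A, noise_cov, 1L)
  var_r <- G0[target, target] - G1[target, target]^2 / G0[target, target]
  log(var_r / noise_cov[target, target])
}

# Exact McNemar p by exhaustive enumeration over all outcomes of b+c fair
# coin tosses (counts weighted by binomial coefficients computed from
# Pascal's rule, no distribution functions involved).
oracle_mcnemar_p <- function(b, c) {
  nd <- b + c
  if (nd == 0) return(1)
  ch <- c(1)
  for (i in seq_len(nd)) ch <- c(ch, 0) + c(0, ch)   # row nd of Pascal
  tail_prob <- sum(ch[seq_len(min(b, c) + 1L)]) / 2^nd
  min(1, 2 * tail_prob)
}

# Brute-force Benjamini-Hochberg adjusted p-values from the definition:
# q_(i) = min over j >= i of min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- pmin(1, m * ps / seq_len(m))
  for (i in (m - 1L):1L) qs[i] <- min(qs[i], qs[i + 1L])
  out <- numeric(m)
  out[ord] <- qs
  out
}

# Exact two-sided signed-rank p by enumeration over all 2^n sign
# assignments of the absolute differences (no ties/zeros assumed).
oracle_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Direct DFT periodogram of a Hann-windowed zero-padded segment, written
# with explicit trigonometric sums.
oracle_periodogram <- function(x, nfft) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  xw <- c(x * w, numeric(nfft - n))
  nb <- nfft %/% 2 + 1
  pw <- numeric(nb)
  tt <- seq_len(nfft) - 1
  for (k in seq_len(nb)) {
    re <- sum(xw * cos(2 * pi * (k - 1) * tt / nfft))
    im <- sum(xw * sin(2 * pi * (k - 1) * tt / nfft))
    pw[k] <- re^2 + im^2
  }
  pw
}

# Direct-loop centered moving average with shrinking symmetric window.
oracle_moving_average <- function(v, w) {
  n <- length(v)
  h <- max(0, floor(w / 2))
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    mean(v[(i - k):(i + k)])
  }, 0)
}
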