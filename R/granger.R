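# Conditional Granger causality from a pooled Gram matrix.
#
# For channels s (source) and t (target), the causal magnitude is
#   F(s -> t) = ln( var(restricted residual of t) / var(full residual of t) )
# where the restricted regression omits all lags of s and the full
# regression uses all channels' lags. Both variances use the same divisor,
# so F reduces to the log ratio of residual sums of squares. Restricted and
# full regressions are solved from sub-blocks of one Gram matrix, which is
# what makes the surrogate loop cheap.

# Residual sum of squares of each target after regressing on the lagged
# columns `zidx` (indices into the n*p lag block).
gram_rss <- function(G, n, p, zidx) {
  m <- n * p
  yi <- m + seq_len(n)
  Syy <- diag(G)[yi]
  if (length(zidx) == 0L) return(Syy)
  Szz <- G[zidx, zidx, drop = FALSE]
  Szy <- G[zidx, yi, drop = FALSE]
  R <- chol(Szz)                         # errors propagate to caller
  Syy - colSums(backsolve(R, Szy, transpose = TRUE)^2)
}

lag_cols <- function(channels, n, p) {
  as.vector(outer(channels, (seq_len(p) - 1L) * n, `+`))
}

# Full n x n conditional-GC matrix from a Gram matrix; entry [i, j] is
# F(j -> i). Failures (e.g. collinear channels) yield NA entries.
gc_from_gram <- function(G, n, p) {
  vals <- matrix(NA_real_, n, n)
  rss_u <- tryCatch(gram_rss(G, n, p, lag_cols(seq_len(n), n, p)),
                    error = function(e) NULL)
  if (is.null(rss_u)) return(list(values = vals, n_failed = n * (n - 1L)))
  n_failed <- 0L
  clipped <- 0L
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(n), j)
    rss_r <- tryCatch(gram_rss(G, n, p, lag_cols(keep, n, p)),
                      error = function(e) NULL)
    if (is.null(rss_r)) { n_failed <- n_failed + n - 1L; next }
    f <- log(rss_r[keep] / rss_u[keep])
    neg <- f < 0
    if (any(neg)) {
      if (any(f < -1e-10)) {
        # nested OLS guarantees rss_r >= rss_u; anything beyond roundoff
        # means the solve was ill-conditioned
        n_failed <- n_failed + sum(f < -1e-10)
        f[f < -1e-10] <- NA_real_
      }
      clipped <- clipped + sum(f < 0 & f >= -1e-10, na.rm = TRUE)
      f[!is.na(f) & f < 0] <- 0
    }
    vals[keep, j] <- f
  }
  list(values = vals, n_failed = n_failed, n_clipped = clipped)
}

#' Conditional Granger causality for one ordered pair
#'
#' Computes the time-domain causal magnitude of `source` on `target`. With
#' `conditional = TRUE` (default) both models include all remaining
#' channels, so influences mediated by third channels are partialled out;
#' with `conditional = FALSE` only the source/target pair enters
#' (pairwise, unconditioned GC).
#'
#' @param x `channels x samples` matrix, list of trials, or [epoch_set()]
#'   (preprocessed; see [preprocess_epoch()]).
#' @param source,target channel labels or indices, distinct.
#' @param p model order shared by the restricted and unrestricted fits.
#' @param conditional condition on the remaining channels?
#' @return causal magnitude in nats (non-negative; values within 1e-10
#'   below zero are clipped to 0, flagged via attribute `"clipped"`).
#' @export
conditional_gc_pair <- function(x, source, target, p, conditional = TRUE) {
  trials <- as_trial_list(x)
  n <- nrow(trials[[1L]])
  labels <- rownames(trials[[1L]]) %||% paste0("ch", seq_len(n))
  if (inherits(x, "epoch_set")) labels <- x$labels
  si <- if (is.character(source)) match(source, labels) else as.integer(source)
  ti <- if (is.character(target)) match(target, labels) else as.integer(target)
  if (is.na(si) || is.na(ti)) stop("unknown source/target channel")
  if (si == ti) stop("source and target must differ")
  gram <- var_gram(trials, p)
  chans <- if (conditional) seq_len(n) else sort(c(si, ti))
  rss_u <- gram_rss(gram$G, n, p, lag_cols(chans, n, p))
  rss_r <- gram_rss(gram$G, n, p, lag_cols(setdiff(chans, si), n, p))
  f <- log(rss_r[ti] / rss_u[ti])
  clipped <- FALSE
  if (f < 0) {
    if (f < -1e-10) stop("negative causal magnitude beyond tolerance (",
                         format(f), "); ill-conditioned fit")
    f <- 0
    clipped <- TRUE
  }
  attr(f, "clipped") <- clipped
  f
}

#' Conditional Granger-causality matrix over all ordered pairs
#'
#' Computes `F(j -> i)` for every ordered channel pair, each conditioned on
#' the remaining `n - 2` channels. The unrestricted model is fitted once;
#' each restricted model (one per source) is solved from sub-blocks of the
#' same Gram matrix. Per-entry failures (e.g. a duplicated channel making
#' the regression collinear) are recorded as `NA` and the matrix is still
#' returned.
#'
#' @inheritParams conditional_gc_pair
#' @return An object of class `gc_matrix`: `values` (`n x n`, `[i, j]` =
#'   `F(j -> i)` in nats, diagonal `NA`), `labels`, `order`, `n_obs`,
#'   `n_failed`, `n_clipped`.
#' @export
gc_matrix <- function(x, p) {
  trials <- as_trial_list(x)
  n <- nrow(trials[[1L]])
  labels <- rownames(trials[[1L]]) %||% paste0("ch", seq_len(n))
  if (inherits(x, "epoch_set")) labels <- x$labels
  gram <- var_gram(trials, p)
  res <- gc_from_gram(gram$G, n, p)
  dimnames(res$values) <- list(labels, labels)
  structure(
    list(values = res$values, labels = labels, order = as.integer(p),
         n_obs = gram$N, n_failed = res$n_failed,
         n_clipped = res$n_clipped %||% 0L),
    class = "gc_matrix"
  )
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat("conditional GC matrix ([i, j] = F(j -> i), nats), order ",
      x$order, ", N = ", x$n_obs, "\n", sep = "")
  print(round(x$values, 4))
  if (x$n_failed > 0) cat("  failed entries:", x$n_failed, "\n")
  invisible(x)
}
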