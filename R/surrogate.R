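#' Phase-randomization surrogate of a multichannel epoch
#'
#' Fourier-transforms each channel, replaces the phases with independent
#' uniform random phases (conjugate-symmetric, so the output is real), and
#' preserves the amplitude spectrum exactly. Phases are drawn independently
#' per channel, destroying all cross-channel dependence: the surrogate
#' realizes the null hypothesis of zero connectivity while keeping each
#' channel's spectrum (hence autocorrelation) intact.
#'
#' @param x numeric `channels x samples` matrix.
#' @param seed optional integer seed.
#' @return surrogate matrix of the same shape.
#' @export
phase_randomize <- function(x, seed = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  with_seed(seed, t(phase_randomize_cols(t(x))))
}

# Core on a samples x columns matrix; every column gets independent phases.
# DC is preserved as-is; for even length the Nyquist bin is kept real
# (its amplitude preserved) so the inverse transform is exactly real.
phase_randomize_cols <- function(xt) {
  T <- nrow(xt)
  Fq <- stats::mvfft(xt)
  half <- if (T %% 2L == 0L) T %/% 2L else (T + 1L) %/% 2L
  idx <- seq.int(2L, half)
  out <- Fq
  ph <- matrix(stats::runif(length(idx) * ncol(xt), 0, 2 * pi),
               length(idx), ncol(xt))
  out[idx, ] <- Mod(Fq[idx, , drop = FALSE]) * exp(1i * ph)
  if (T %% 2L == 0L) out[half + 1L, ] <- Mod(Fq[half + 1L, , drop = FALSE])
  out[T - idx + 2L, ] <- Conj(out[idx, , drop = FALSE])
  Re(stats::mvfft(out, inverse = TRUE)) / T
}

# Null distribution of the conditional-GC matrix under phase randomization.
# Returns an n x n x n_surrogates array. The surrogate schedule is
# deterministic: a single RNG stream seeded once, phases drawn in a fixed
# chunked order. FFTs are batched across surrogates (single trial) or
# across trials (ensemble) for speed.
surrogate_gc_null <- function(trials, p, n_surrogates, seed = NULL) {
  n <- nrow(trials[[1L]])
  Tlen <- vapply(trials, ncol, 0L)
  if (length(unique(Tlen)) != 1L) {
    stop("surrogate batching requires equal-length trials")
  }
  T <- Tlen[1L]
  K <- length(trials)
  nulls <- array(NA_real_, c(n, n, n_surrogates))
  with_seed(seed, {
    if (K == 1L) {
      xt <- t(trials[[1L]])
      Fq <- stats::mvfft(xt)
      amp <- Mod(Fq)
      half <- if (T %% 2L == 0L) T %/% 2L else (T + 1L) %/% 2L
      idx <- seq.int(2L, half)
      conj_idx <- T - idx + 2L
      # cap chunk memory: at most ~4e6 matrix elements per FFT batch
      chunk <- max(1L, min(2400L %/% n, ceiling(4e6 / (T * n))))
      s0 <- 0L
      while (s0 < n_surrogates) {
        sc <- min(chunk, n_surrogates - s0)
        rep_cols <- rep(seq_len(n), sc)
        FB <- matrix(0i, T, n * sc)
        ph <- matrix(stats::runif(length(idx) * n * sc, 0, 2 * pi),
                     length(idx), n * sc)
        FB[idx, ] <- amp[idx, rep_cols, drop = FALSE] * exp(1i * ph)
        FB[1L, ] <- Fq[1L, rep_cols]
        if (T %% 2L == 0L) FB[half + 1L, ] <- amp[half + 1L, rep_cols]
        FB[conj_idx, ] <- Conj(FB[idx, , drop = FALSE])
        XB <- Re(stats::mvfft(FB, inverse = TRUE)) / T
        WB <- var_embed(XB, p)
        ncolsB <- n * sc
        for (s in seq_len(sc)) {
          cols <- as.vector(outer((s - 1L) * n + seq_len(n),
                                  (0:p) * ncolsB, `+`))
          G <- crossprod(WB[, cols, drop = FALSE])
          nulls[, , s0 + s] <- gc_from_gram(G, n, p)$values
        }
        s0 <- s0 + sc
      }
    } else {
      xt_all <- do.call(cbind, lapply(trials, t))   # T x (n*K)
      Fq <- stats::mvfft(xt_all)
      amp <- Mod(Fq)
      half <- if (T %% 2L == 0L) T %/% 2L else (T + 1L) %/% 2L
      idx <- seq.int(2L, half)
      conj_idx <- T - idx + 2L
      nc <- n * K
      trial_cols <- lapply(seq_len(K), function(k) {
        as.vector(outer((k - 1L) * n + seq_len(n), (0:p) * nc, `+`))
      })
      for (s in seq_len(n_surrogates)) {
        FB <- matrix(0i, T, nc)
        ph <- matrix(stats::runif(length(idx) * nc, 0, 2 * pi),
                     length(idx), nc)
        FB[idx, ] <- amp[idx, , drop = FALSE] * exp(1i * ph)
        FB[1L, ] <- Fq[1L, ]
        if (T %% 2L == 0L) FB[half + 1L, ] <- amp[half + 1L, ]
        FB[conj_idx, ] <- Conj(FB[idx, , drop = FALSE])
        XB <- Re(stats::mvfft(FB, inverse = TRUE)) / T
        WB <- var_embed(XB, p)
        G <- matrix(0, n * (p + 1L), n * (p + 1L))
        for (k in seq_len(K)) {
          G <- G + crossprod(WB[, trial_cols[[k]], drop = FALSE])
        }
        nulls[, , s] <- gc_from_gram(G, n, p)$values
      }
    }
  })
  nulls
}

#' Edge significance against a phase-randomization null
#'
#' Computes the observed conditional-GC matrix, builds a per-edge null
#' distribution from `n_surrogates` phase-randomized copies of the data
#' (each trial randomized independently for ensembles), converts each edge
#' to an add-one permutation-style p-value
#' `p = (1 + #\{null >= observed\}) / (n_surrogates + 1)`, adjusts the
#' `n(n-1)` off-diagonal p-values by Benjamini–Hochberg FDR, and thresholds
#' the adjusted values at `alpha`.
#'
#' @inheritParams gc_matrix
#' @param n_surrogates number of surrogate datasets (>= 100).
#' @param alpha FDR threshold on the adjusted p-values (default 0.01).
#' @param seed integer seed for the surrogate schedule.
#' @return An object of class `edge_graph`: `adjacency` (boolean, `[i, j]`
#'   means edge `j -> i` significant), `pvalues`, `qvalues`, `out_degree`
#'   (per-region significant outgoing edges), `gc` (the observed
#'   [gc_matrix()]), `labels`, `alpha`, `n_surrogates`.
#' @export
edge_significance <- function(x, p, n_surrogates = 2000L, alpha = 0.01,
                              seed = NULL) {
  stopifnot(n_surrogates >= 100L, alpha > 0, alpha < 1)
  trials <- as_trial_list(x)
  obs <- gc_matrix(x, p)
  nulls <- surrogate_gc_null(trials, p, n_surrogates, seed = seed)
  n <- length(obs$labels)
  pvals <- matrix(NA_real_, n, n, dimnames = dimnames(obs$values))
  degenerate <- FALSE
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i == j || is.na(obs$values[i, j])) next
    nv <- nulls[i, j, ]
    nv <- nv[!is.na(nv)]
    if (length(nv) == 0L) next
    if (length(unique(nv)) == 1L) degenerate <- TRUE
    pvals[i, j] <- (1 + sum(nv >= obs$values[i, j])) / (n_surrogates + 1)
  }
  if (degenerate) {
    warning("all-identical null values on some edge; p-value precision ",
            "is limited")
  }
  off <- which(row(pvals) != col(pvals))
  qvals <- pvals
  qvals[off] <- stats::p.adjust(pvals[off], method = "BH")
  adjacency <- !is.na(qvals) & qvals < alpha
  diag(adjacency) <- FALSE
  out_degree <- colSums(adjacency)
  names(out_degree) <- obs$labels
  structure(
    list(adjacency = adjacency, pvalues = pvals, qvalues = qvals,
         out_degree = out_degree, gc = obs, labels = obs$labels,
         alpha = alpha, n_surrogates = as.integer(n_surrogates)),
    class = "edge_graph"
  )
}

#' @export
print.edge_graph <- function(x, ...) {
  cat("edge graph at FDR-adjusted alpha =", x$alpha, "(",
      x$n_surrogates, "surrogates )\n")
  cat("  significant edges:", sum(x$adjacency), "\n")
  cat("  out-degree:",
      paste(sprintf("%s=%d", x$labels, x$out_degree), collapse = " "), "\n")
  invisible(x)
}

#' Group-level edge proportion and consensus network
#'
#' Element-wise proportion of sessions whose edge graph marks each directed
#' edge significant, P(edge), with a consensus network of edges present in
#' at least `threshold` (default 90%) of sessions.
#'
#' @param graphs non-empty list of [edge_significance()] results sharing
#'   labels.
#' @param threshold consensus proportion (inclusive).
#' @return An object of class `group_network`: `p_edge`, `consensus`,
#'   `n_sessions`, `labels`, `threshold`.
#' @export
group_edge_proportion <- function(graphs, threshold = 0.9) {
  if (length(graphs) == 0L) stop("empty graph list")
  labels <- graphs[[1L]]$labels
  for (g in graphs) {
    stopifnot(inherits(g, "edge_graph"))
    if (!identical(g$labels, labels)) stop("graphs must share labels")
  }
  p_edge <- Reduce(`+`, lapply(graphs, function(g) g$adjacency * 1)) /
    length(graphs)
  consensus <- p_edge >= threshold
  diag(consensus) <- FALSE
  structure(
    list(p_edge = p_edge, consensus = consensus,
         n_sessions = length(graphs), labels = labels,
         threshold = threshold),
    class = "group_network"
  )
}

#' Exact McNemar p-value for paired binary outcomes
#'
#' Exact binomial two-sided test on the discordant-pair counts:
#' `p = 2 * P(Bin(b + c, 1/2) <= min(b, c))`, capped at 1. With no
#' discordant pairs the p-value is 1 by convention.
#'
#' @param b,c discordant counts (present-in-A-only, present-in-B-only).
#' @return p-value in (0, 1].
#' @export
mcnemar_exact_p <- function(b, c) {
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  nd <- b + c
  if (nd == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
}

#' Paired-condition edge comparison by exact McNemar tests
#'
#' For every directed edge, builds the 2x2 table of paired
#' presence/absence across two session-paired condition lists, computes
#' the exact McNemar p-value on the discordant counts, and adjusts across
#' edges by Benjamini–Hochberg FDR.
#'
#' @param graphs_A,graphs_B equal-length lists of [edge_significance()]
#'   results, element `k` of each coming from the same session/subject.
#' @param alpha significance threshold on adjusted p-values (default 0.05).
#' @return An object of class `mcnemar_edges`: data frame `edges` (source,
#'   target, counts `n11/n10/n01/n00`, `b`, `c`, `p`, `q`, `significant`,
#'   `degenerate` flag for `b + c = 0`), plus `labels`, `n_pairs`.
#' @export
mcnemar_condition_test <- function(graphs_A, graphs_B, alpha = 0.05) {
  stopifnot(length(graphs_A) == length(graphs_B), length(graphs_A) >= 1L)
  labels <- graphs_A[[1L]]$labels
  for (g in c(graphs_A, graphs_B)) {
    if (!identical(g$labels, labels)) stop("graphs must share labels")
  }
  n <- length(labels)
  rows <- list()
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i == j) next
    a_has <- vapply(graphs_A, function(g) g$adjacency[i, j], FALSE)
    b_has <- vapply(graphs_B, function(g) g$adjacency[i, j], FALSE)
    n11 <- sum(a_has & b_has); n10 <- sum(a_has & !b_has)
    n01 <- sum(!a_has & b_has); n00 <- sum(!a_has & !b_has)
    rows[[length(rows) + 1L]] <- data.frame(
      source = labels[j], target = labels[i],
      n11 = n11, n10 = n10, n01 = n01, n00 = n00,
      b = n10, c = n01,
      p = mcnemar_exact_p(n10, n01),
      degenerate = (n10 + n01) == 0L,
      stringsAsFactors = FALSE
    )
  }
  edges <- do.call(rbind, rows)
  edges$q <- stats::p.adjust(edges$p, method = "BH")
  edges$significant <- edges$q < alpha
  structure(
    list(edges = edges, labels = labels, n_pairs = length(graphs_A),
         alpha = alpha),
    class = "mcnemar_edges"
  )
}
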