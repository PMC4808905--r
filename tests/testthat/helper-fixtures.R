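# Small builders shared across test files.

bivariate_coupled_spec <- function(coupling = 0.4) {
  var_spec(list(matrix(c(0.5, 0, coupling, 0.5), 2, 2)),
           labels = c("X1", "X2"))
}

# 3-channel chain X3 -> X2 -> X1 (lag-1 couplings), used to separate
# conditional from marginal causality.
chain_spec <- function(coupling = 0.5) {
  A <- diag(0.4, 3)
  A[2, 3] <- coupling
  A[1, 2] <- coupling
  var_spec(list(A), labels = c("X1", "X2", "X3"))
}

# six independent AR(2) channels with the shipped self-dynamics
independent_ar2_spec <- function() hub_var_spec("null")

white_epochs <- function(n_trials, n_channels = 3L, T = 100L, seed = 1L,
                         labels = paste0("ch", seq_len(n_channels))) {
  trials <- gcflow:::with_seed(seed, lapply(seq_len(n_trials), function(k) {
    matrix(rnorm(n_channels * T), n_channels, T,
           dimnames = list(labels, NULL))
  }))
  meta <- data.frame(rt = seq_len(n_trials) / 10 + 0.5,
                     condition = "A", subject = "S01")
  epoch_set(trials, meta, fs = 250, labels = labels)
}

# fabricate an edge_graph with a given out-degree vector (plumbing for
# hub-classification and group-level tests)
fake_graph <- function(out_degree, labels = names(out_degree)) {
  n <- length(out_degree)
  adjacency <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (j in seq_len(n)) {
    if (out_degree[j] > 0) {
      targets <- setdiff(seq_len(n), j)[seq_len(out_degree[j])]
      adjacency[targets, j] <- TRUE
    }
  }
  structure(list(adjacency = adjacency,
                 pvalues = matrix(NA_real_, n, n),
                 qvalues = matrix(NA_real_, n, n),
                 out_degree = colSums(adjacency) |> stats::setNames(labels),
                 labels = labels, alpha = 0.05, n_surrogates = 0L),
            class = "edge_graph")
}

# fabricated trial records for the statistics layer
fake_records <- function(n_per_cell, subjects, conditions, hubs, rts) {
  rows <- list()
  for (s in subjects) for (cd in conditions) {
    for (h in names(n_per_cell)) {
      k <- n_per_cell[[h]]
      if (k == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, condition = cd, hub = h,
        rt = rts(h, k), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$trial <- seq_len(nrow(out))
  out
}
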