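test_that("phase randomization preserves spectra and destroys coupling", {
  spec <- bivariate_coupled_spec(0.45)
  x <- simulate_var(spec, 4096, seed = 61)
  s <- phase_randomize(x, seed = 62)

  # per-channel amplitude spectrum preserved essentially exactly
  for (ch in 1:2) {
    expect_equal(Mod(fft(s[ch, ])), Mod(fft(x[ch, ])), tolerance = 1e-8)
  }
  # mean and variance preserved (Parseval)
  expect_equal(rowMeans(s), rowMeans(x), tolerance = 1e-8)
  expect_equal(apply(s, 1, var), apply(x, 1, var), tolerance = 1e-8)

  # strong observed cross-correlation, none in the surrogate at any lag
  T <- ncol(x)
  ccf_max <- function(m) {
    cc <- ccf(m[1, ], m[2, ], lag.max = 5, plot = FALSE)$acf
    max(abs(cc))
  }
  expect_gt(ccf_max(x), 0.2)
  expect_lt(ccf_max(s), 3 / sqrt(T))

  # deterministic under a fixed seed
  expect_identical(phase_randomize(x, seed = 63),
                   phase_randomize(x, seed = 63))
})

test_that("add-one p-values obey their exact bounds and extremes", {
  set.seed(64)
  # white noise with one strongly coupled pair
  A <- matrix(0, 3, 3); diag(A) <- 0.3; A[1, 2] <- 0.6
  spec <- var_spec(list(A), labels = c("a", "b", "c"))
  x <- preprocess_epoch(simulate_var(spec, 2000, seed = 65))
  eg <- edge_significance(x, 1, n_surrogates = 200, alpha = 0.05,
                          seed = 66)
  off <- eg$pvalues[row(eg$pvalues) != col(eg$pvalues)]
  expect_true(all(off >= 1 / 201 & off <= 1))
  # the planted edge dominates every surrogate: p hits the exact floor
  expect_equal(eg$pvalues[1, 2], 1 / 201)
  expect_true(eg$adjacency[1, 2])
  # out-degree counts significant outgoing edges per source column
  expect_equal(unname(eg$out_degree), unname(colSums(eg$adjacency)))
  # determinism of the whole surrogate schedule
  eg2 <- edge_significance(x, 1, n_surrogates = 200, alpha = 0.05,
                           seed = 66)
  expect_identical(eg$pvalues, eg2$pvalues)
})

test_that("null raw p-values are approximately uniform", {
  # zero-connectivity truth: per-edge p over replicate sessions ~ U(0,1)
  spec <- independent_ar2_spec()
  pvals <- c()
  for (s in 1:30) {
    x <- preprocess_epoch(simulate_var(spec, 250, seed = 1200 + s))
    eg <- edge_significance(x, 2, n_surrogates = 100, alpha = 0.01,
                            seed = 1300 + s)
    pvals <- c(pvals, eg$pvalues[row(eg$pvalues) != col(eg$pvalues)])
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
})

test_that("BH adjustment matches the brute-force definition", {
  set.seed(67)
  for (rep in 1:20) {
    p <- runif(30)^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p),
                 tolerance = 1e-12)
  }
  # monotonicity: adjusted >= raw, non-decreasing in raw-p order
  p <- runif(30)
  q <- p.adjust(p, method = "BH")
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("group proportion and consensus follow the inclusive 0.9 rule", {
  labels <- c("ACC", "MCC", "lSMC", "rSMC", "PCC", "ESC")
  g1 <- fake_graph(c(ACC = 2, MCC = 0, lSMC = 0, rSMC = 0, PCC = 3,
                     ESC = 0))
  # unanimity
  gp <- group_edge_proportion(rep(list(g1), 10))
  expect_true(all(gp$p_edge %in% c(0, 1)))
  expect_equal(gp$consensus, g1$adjacency)

  # 9 of 10: p_edge = 0.9 counts as consensus (inclusive threshold)
  g0 <- fake_graph(c(ACC = 0, MCC = 0, lSMC = 0, rSMC = 0, PCC = 0,
                     ESC = 0))
  gp2 <- group_edge_proportion(c(rep(list(g1), 9), list(g0)))
  expect_equal(max(gp2$p_edge), 0.9)
  expect_equal(gp2$consensus, g1$adjacency)

  # binomial tail: independent edge-wise coin flips, 20 sessions
  set.seed(68)
  n <- 6
  flips <- lapply(1:20, function(i) {
    adjacency <- matrix(runif(n * n) < 0.5, n, n,
                        dimnames = list(labels, labels))
    diag(adjacency) <- FALSE
    structure(list(adjacency = adjacency, labels = labels),
              class = "edge_graph")
  })
  gp3 <- group_edge_proportion(flips)
  expected <- n * (n - 1) * pbinom(17, 20, 0.5, lower.tail = FALSE)
  expect_lt(abs(sum(gp3$consensus) - expected), 3 + 3 * sqrt(expected))
  expect_error(group_edge_proportion(list()), "empty")
})

test_that("exact McNemar p agrees with exhaustive enumeration", {
  # symmetric discordance: p = 1
  expect_equal(mcnemar_exact_p(4, 4), 1)
  expect_equal(mcnemar_exact_p(0, 0), 1)
  # one-sided extreme: 2 * (1/2)^10
  expect_equal(mcnemar_exact_p(10, 0), 2 * 0.5^10, tolerance = 1e-12)
  # all tables with b + c <= 20 match the enumeration oracle exactly
  for (nd in 0:20) for (b in 0:nd) {
    expect_equal(mcnemar_exact_p(b, nd - b), oracle_mcnemar_p(b, nd - b),
                 tolerance = 1e-12)
  }
})

test_that("condition comparison flags planted edge differences", {
  gA <- fake_graph(c(a = 1, b = 0, c = 0), labels = c("a", "b", "c"))
  g0 <- fake_graph(c(a = 0, b = 0, c = 0), labels = c("a", "b", "c"))
  # edge a->b present in all 12 A-sessions, never in B
  mc <- mcnemar_condition_test(rep(list(gA), 12), rep(list(g0), 12))
  row_ab <- mc$edges[mc$edges$source == "a" & mc$edges$target == "b", ]
  expect_equal(row_ab$b, 12)
  expect_equal(row_ab$p, 2 * 0.5^12)
  expect_true(row_ab$significant)
  # undisturbed edges are degenerate with p = 1
  other <- mc$edges[!(mc$edges$source == "a" & mc$edges$target == "b"), ]
  expect_true(all(other$degenerate))
  expect_true(all(other$p == 1))
})
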