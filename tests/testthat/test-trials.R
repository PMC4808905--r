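test_that("hub classification takes the unique out-degree maximum", {
  labels <- c("ACC", "MCC", "lSMC", "rSMC", "PCC", "ESC")
  od <- function(v) stats::setNames(v, labels)
  expect_equal(classify_trial_hub(od(c(3, 1, 0, 0, 0, 0))), "ACC")
  expect_equal(classify_trial_hub(od(c(2, 2, 0, 0, 0, 0))), "discarded-tie")
  expect_equal(classify_trial_hub(od(c(0, 0, 0, 0, 0, 0))), "discarded-tie")
  expect_equal(classify_trial_hub(od(c(0, 1, 0, 0, 5, 1))), "PCC")
})

test_that("single-trial networks recover planted hubs and normalize outflow", {
  scn <- scenario(
    regime_probs = list("K+" = c("MCC-hub" = 0.5, "PCC-hub" = 0.5)),
    n_trials = 40, n_subjects = 1, seed = 71
  )
  ep <- build_scenario(scn)
  tn <- trial_networks(ep, p = 2, n_surrogates = 200, alpha = 0.05,
                       seed = 72)
  # normalization: sums to 1 whenever any edge is significant
  has_edges <- tn$records$n_edges > 0
  expect_true(all(abs(rowSums(tn$outflow[has_edges, ]) - 1) < 1e-12))
  expect_true(all(rowSums(tn$outflow[!has_edges, , drop = FALSE]) == 0))
  # majority of classified trials match the planted regime
  cls <- tn$records$hub != "discarded-tie"
  truth_hub <- sub("-hub", "", tn$records$regime_truth)
  acc <- mean(tn$records$hub[cls] == truth_hub[cls])
  expect_gt(acc, 0.7)
  # determinism
  tn2 <- trial_networks(ep, p = 2, n_surrogates = 200, alpha = 0.05,
                        seed = 72)
  expect_identical(tn$records, tn2$records)
})

test_that("hub percentages bookkeep to 100 and the ANOVA matches its oracle", {
  set.seed(73)
  recs <- fake_records(
    n_per_cell = list(MCC = 12, PCC = 8, ACC = 3, `discarded-tie` = 7),
    subjects = sprintf("S%02d", 1:6), conditions = c("K+", "K-"),
    hubs = NULL, rts = function(h, k) rlnorm(k)
  )
  # perturb counts per subject/condition to make cells unequal
  an <- hub_percentage_anova(recs, hubs = c("MCC", "PCC"))
  # bookkeeping: MCC% + PCC% + other% + discard% = 100 per cell
  for (s in unique(recs$subject)) for (cd in c("K+", "K-")) {
    r <- recs[recs$subject == s & recs$condition == cd, ]
    parts <- c(mean(r$hub == "MCC"), mean(r$hub == "PCC"),
               mean(!r$hub %in% c("MCC", "PCC", "discarded-tie")),
               mean(r$hub == "discarded-tie"))
    expect_equal(sum(parts) * 100, 100)
  }
  # identical percentages in every cell: F = 0, p = 1
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)

  # jittered table: F equals the squared paired-t statistic (independent
  # implementation via t.test on the double difference)
  recs2 <- recs
  flip <- sample(which(recs2$hub == "PCC" & recs2$condition == "K-"), 20)
  recs2$hub[flip] <- "MCC"
  an2 <- hub_percentage_anova(recs2, hubs = c("MCC", "PCC"))
  w <- an2$table
  d <- (w[, 1] - w[, 3]) - (w[, 2] - w[, 4])
  tt <- t.test(d)
  expect_equal(an2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an2$p, tt$p.value, tolerance = 1e-10)

  # denominator switch: classified-only percentages are larger
  an3 <- hub_percentage_anova(recs, denominator = "classified")
  expect_true(all(an3$table >= an$table))
})

test_that("interaction is detected when the hub mixture shifts between conditions", {
  set.seed(74)
  detected <- 0L
  for (rep in 1:5) {
    rows <- list()
    for (s in sprintf("S%02d", 1:10)) {
      for (cd in c("K+", "K-")) {
        pr <- if (cd == "K+") c(0.3, 0.3, 0.4) else c(0.2, 0.4, 0.4)
        hub <- sample(c("MCC", "PCC", "discarded-tie"), 400, TRUE, pr)
        rows[[paste(s, cd)]] <- data.frame(
          subject = s, condition = cd, hub = hub, rt = rlnorm(400),
          stringsAsFactors = FALSE)
      }
    }
    an <- hub_percentage_anova(do.call(rbind, rows), hubs = c("MCC", "PCC"))
    if (an$p < 0.05) detected <- detected + 1L
  }
  expect_gte(detected, 3L)
})

test_that("RT comparison recovers a planted median gap and matches the
           signed-rank oracle", {
  set.seed(75)
  recs <- fake_records(
    n_per_cell = list(MCC = 30, PCC = 30),
    subjects = sprintf("S%02d", 1:10), conditions = c("K+", "K-"),
    hubs = NULL,
    rts = function(h, k) rlnorm(k, log(ifelse(h == "PCC", 1.3, 1.0)), 0.3)
  )
  res <- rt_by_hub_comparison(recs, hubs = c("PCC", "MCC"))
  pooled <- res$tests[res$tests$comparison == "pooled", ]
  expect_lt(abs(pooled$median_diff - 0.3), 0.1)
  expect_true(pooled$q < 0.05)

  # test statistic and p match exhaustive sign-assignment enumeration
  med <- res$medians[res$medians$comparison == "pooled", ]
  d <- med$median_A - med$median_B
  expect_equal(pooled$p, oracle_signed_rank_p(d), tolerance = 1e-10)

  # null: no planted difference, difference estimate near zero
  recs0 <- fake_records(
    n_per_cell = list(MCC = 40, PCC = 40),
    subjects = sprintf("S%02d", 1:8), conditions = "A", hubs = NULL,
    rts = function(h, k) rlnorm(k, 0, 0.3)
  )
  res0 <- rt_by_hub_comparison(recs0, hubs = c("PCC", "MCC"),
                               by_condition = FALSE)
  expect_lt(abs(res0$tests$median_diff), 0.15)
})

test_that("RT-sorted curves smooth correctly and find a planted crossover", {
  # smoothing identity on a constant trace; oracle agreement on noise
  set.seed(76)
  v <- runif(120)
  for (w in c(1, 5, 12, 31)) {
    expect_equal(gcflow:::moving_average_centered(v, w),
                 oracle_moving_average(v, w), tolerance = 1e-12)
  }
  expect_equal(gcflow:::moving_average_centered(rep(0.4, 50), 5),
               rep(0.4, 50))

  # interior mean preservation
  sm <- gcflow:::moving_average_centered(v, 11)
  expect_equal(mean(sm[20:100]), mean(sapply(20:100, function(i) {
    mean(v[(i - 5):(i + 5)])
  })), tolerance = 1e-12)

  # planted step: PCC dominates fast trials, MCC slow ones
  n <- 200
  rt <- sort(rlnorm(n, 0, 0.4))
  hub <- c(rep("PCC", n / 2), rep("MCC", n / 2))
  outflow <- matrix(0, n, 2, dimnames = list(NULL, c("MCC", "PCC")))
  outflow[hub == "PCC", "PCC"] <- 0.8; outflow[hub == "PCC", "MCC"] <- 0.2
  outflow[hub == "MCC", "MCC"] <- 0.8; outflow[hub == "MCC", "PCC"] <- 0.2
  shuf <- sample(n)
  nets <- list(records = data.frame(rt = rt[shuf], hub = hub[shuf]),
               outflow = outflow[shuf, ])
  curve <- rt_sorted_outdegree(nets, regions = c("MCC", "PCC"))
  expect_equal(curve$window, 20)
  expect_false(is.unsorted(curve$rt_grid))
  k <- length(curve$rt_grid)
  expect_gt(mean(curve$curves[1:40, "PCC"] - curve$curves[1:40, "MCC"]), 0.4)
  expect_lt(mean(curve$curves[(k - 39):k, "PCC"] -
                 curve$curves[(k - 39):k, "MCC"]), -0.4)
  # crossover within a window of the planted boundary
  sgn <- sign(curve$curves[, "PCC"] - curve$curves[, "MCC"])
  cross <- which(diff(sgn) != 0)
  expect_true(all(abs(cross - n / 2) <= curve$window + 1))
  # difference flagged significant away from the crossover
  expect_true(any(curve$sig_mask[1:40]))
  expect_true(any(curve$sig_mask[(k - 39):k]))

  # degenerate inputs
  nets$records$hub <- "discarded-tie"
  expect_error(rt_sorted_outdegree(nets), "tie-discarded")
})
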