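#' Classify the causal hub of a single-trial network
#'
#' The causal hub is the region with the highest out-degree (number of
#' significant outgoing edges). Any tie for the maximum — including the
#' all-zero graph — discards the trial.
#'
#' @param graph an [edge_significance()] result for one trial, or a named
#'   out-degree vector.
#' @return hub label, or `"discarded-tie"`.
#' @export
classify_trial_hub <- function(graph) {
  od <- if (inherits(graph, "edge_graph")) graph$out_degree else graph
  stopifnot(is.numeric(od), !is.null(names(od)))
  mx <- max(od)
  if (mx == 0 || sum(od == mx) > 1L) return("discarded-tie")
  names(od)[which.max(od)]
}

#' Single-trial network estimation and hub classification
#'
#' Runs [edge_significance()] on every trial separately (per-trial
#' surrogate null; defaults 200 surrogates at FDR-adjusted alpha 0.05,
#' lighter than the session-level 2000/0.01 and configurable), classifies
#' each trial's causal hub, and records the normalized outflow profile:
#' each region's out-degree divided by the total number of significant
#' outgoing links in the trial (all zeros when the graph is empty).
#'
#' @param epochs an [epoch_set()] of preprocessed trials (preprocessing is
#'   applied internally when `preprocess = TRUE`).
#' @param p model order shared by all trials.
#' @param n_surrogates per-trial surrogate count.
#' @param alpha per-trial FDR-adjusted significance threshold.
#' @param seed master seed; per-trial seeds are derived deterministically.
#' @param preprocess detrend/center each trial first?
#' @return An object of class `trial_networks`: `records` data frame (trial,
#'   subject, condition, rt, regime_truth when available, hub, n_edges),
#'   `outflow` (trials x regions normalized outflow matrix), `graphs`
#'   (list of per-trial `edge_graph`s), `labels`.
#' @export
trial_networks <- function(epochs, p, n_surrogates = 200L, alpha = 0.05,
                           seed = NULL, preprocess = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_trials <- length(epochs$trials)
  seeds <- derive_seeds(seed %||% 1L, n_trials)
  labels <- epochs$labels
  graphs <- vector("list", n_trials)
  hub <- character(n_trials)
  outflow <- matrix(0, n_trials, length(labels),
                    dimnames = list(NULL, labels))
  n_edges <- integer(n_trials)
  for (k in seq_len(n_trials)) {
    xk <- epochs$trials[[k]]
    if (preprocess) xk <- preprocess_epoch(xk)
    g <- edge_significance(xk, p, n_surrogates = n_surrogates,
                           alpha = alpha, seed = seeds[k])
    graphs[[k]] <- g
    hub[k] <- classify_trial_hub(g)
    tot <- sum(g$out_degree)
    n_edges[k] <- tot
    if (tot > 0) outflow[k, ] <- g$out_degree / tot
  }
  records <- data.frame(
    trial = epochs$meta$trial, subject = epochs$meta$subject,
    condition = epochs$meta$condition, rt = epochs$meta$rt,
    hub = hub, n_edges = n_edges, stringsAsFactors = FALSE
  )
  if (!is.null(epochs$meta$regime_truth)) {
    records$regime_truth <- epochs$meta$regime_truth
  }
  structure(
    list(records = records, outflow = outflow, graphs = graphs,
         labels = labels, alpha = alpha,
         n_surrogates = as.integer(n_surrogates)),
    class = "trial_networks"
  )
}

#' @export
print.trial_networks <- function(x, ...) {
  cat("trial networks:", nrow(x$records), "trials (",
      x$n_surrogates, "surrogates/trial, alpha =", x$alpha, ")\n")
  print(round(100 * table(x$records$hub) / nrow(x$records), 1))
  invisible(x)
}

#' Hub-percentage table and 2x2 repeated-measures ANOVA
#'
#' Builds, per subject and condition, the percentage of trials dominated by
#' each of two hubs, then tests the feedback-by-region interaction with a
#' two-way (2 conditions x 2 hub regions) within-subject ANOVA. The
#' interaction F is computed directly as the squared paired-t statistic on
#' the per-subject double difference
#' `(hubA - hubB | cond1) - (hubA - hubB | cond2)`, with
#' `df = (1, n_subjects - 1)`.
#'
#' Denominator convention: with `denominator = "all"` (default),
#' tie-discarded trials stay in the denominator (percentages are of all
#' trials); `"classified"` restricts the denominator to classified trials.
#'
#' @param records the `records` data frame of [trial_networks()] (or any
#'   data frame with `subject`, `condition`, `hub`).
#' @param hubs two region labels to compare.
#' @param conditions two condition labels; defaults to the two present.
#' @param denominator `"all"` or `"classified"`.
#' @return An object of class `hub_anova`: `table` (subject x cell
#'   percentages), `F`, `p`, `df`, `cell_means`, `n_subjects`,
#'   `discard_pct` bookkeeping.
#' @export
hub_percentage_anova <- function(records, hubs = c("MCC", "PCC"),
                                 conditions = NULL,
                                 denominator = c("all", "classified")) {
  denominator <- match.arg(denominator)
  stopifnot(length(hubs) == 2L)
  if (is.null(conditions)) conditions <- sort(unique(records$condition))
  stopifnot(length(conditions) == 2L)
  subjects <- sort(unique(records$subject))
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  pct <- function(sub, cond, h) {
    r <- records[records$subject == sub & records$condition == cond, ]
    if (nrow(r) == 0L) return(NA_real_)
    denom <- if (denominator == "all") nrow(r) else
      sum(r$hub != "discarded-tie")
    if (denom == 0L) return(NA_real_)
    100 * sum(r$hub == h) / denom
  }
  tab <- expand.grid(subject = subjects, condition = conditions,
                     hub = hubs, stringsAsFactors = FALSE)
  tab$pct <- mapply(pct, tab$subject, tab$condition, tab$hub)
  # expand.grid varies subject fastest, so the columns come out in order
  # (cond1, hubA), (cond2, hubA), (cond1, hubB), (cond2, hubB)
  wide <- matrix(tab$pct, nrow = length(subjects))
  rownames(wide) <- subjects
  colnames(wide) <- c(paste(conditions[1], hubs[1], sep = ":"),
                      paste(conditions[2], hubs[1], sep = ":"),
                      paste(conditions[1], hubs[2], sep = ":"),
                      paste(conditions[2], hubs[2], sep = ":"))
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warning("dropping subject(s) with empty cells: ",
            paste(subjects[!complete], collapse = ", "))
    wide <- wide[complete, , drop = FALSE]
  }
  ns <- nrow(wide)
  if (ns < 2L) stop("fewer than 2 subjects with complete cells")
  # double difference per subject: (A - B | cond1) - (A - B | cond2)
  d <- (wide[, 1L] - wide[, 3L]) - (wide[, 2L] - wide[, 4L])
  mbar <- mean(d)
  se <- stats::sd(d) / sqrt(ns)
  if (se == 0) {
    Fstat <- if (mbar == 0) 0 else Inf
    pval <- if (mbar == 0) 1 else 0
  } else {
    tstat <- mbar / se
    Fstat <- tstat^2
    pval <- stats::pf(Fstat, 1, ns - 1, lower.tail = FALSE)
  }
  discard <- vapply(seq_len(ns), function(i) {
    sub <- rownames(wide)[i]
    r <- records[records$subject == sub, ]
    100 * mean(r$hub == "discarded-tie")
  }, 0)
  structure(
    list(table = wide, F = Fstat, p = pval, df = c(1L, ns - 1L),
         cell_means = colMeans(wide), n_subjects = ns,
         hubs = hubs, conditions = conditions,
         discard_pct = stats::setNames(discard, rownames(wide))),
    class = "hub_anova"
  )
}

#' @export
print.hub_anova <- function(x, ...) {
  cat("2x2 repeated-measures ANOVA on hub percentages (",
      paste(x$hubs, collapse = " vs "), "; ",
      paste(x$conditions, collapse = " vs "), ")\n", sep = "")
  print(round(x$cell_means, 1))
  cat("  interaction F(", x$df[1], ",", x$df[2], ") = ",
      format(x$F, digits = 4), ", p = ", format(x$p, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Reaction-time comparison between hub-dominated trial groups
#'
#' Aggregates to per-subject median RT within each hub group (optionally
#' within each condition), then compares groups with a paired Wilcoxon
#' signed-rank test across subjects, Benjamini–Hochberg-adjusted over the
#' family of comparisons.
#'
#' @param records as in [hub_percentage_anova()]; needs `rt` and `hub`.
#' @param hubs two hub labels to compare.
#' @param by_condition compare within each condition separately (plus the
#'   pooled comparison)?
#' @param alpha threshold on adjusted p-values.
#' @return An object of class `rt_comparison`: data frame `tests`
#'   (comparison, n_subjects, median per group, median difference, V, p,
#'   q, significant) and the per-subject median table `medians`.
#' @export
rt_by_hub_comparison <- function(records, hubs = c("MCC", "PCC"),
                                 by_condition = TRUE, alpha = 0.05) {
  stopifnot(length(hubs) == 2L)
  groups <- list(pooled = records)
  if (by_condition) {
    for (cond in sort(unique(records$condition))) {
      groups[[cond]] <- records[records$condition == cond, ]
    }
  }
  med_tab <- list()
  rows <- list()
  for (gname in names(groups)) {
    r <- groups[[gname]]
    subjects <- sort(unique(r$subject))
    mA <- mB <- rep(NA_real_, length(subjects))
    for (i in seq_along(subjects)) {
      rA <- r$rt[r$subject == subjects[i] & r$hub == hubs[1L]]
      rB <- r$rt[r$subject == subjects[i] & r$hub == hubs[2L]]
      if (length(rA)) mA[i] <- stats::median(rA)
      if (length(rB)) mB[i] <- stats::median(rB)
    }
    ok <- !is.na(mA) & !is.na(mB)
    if (sum(ok) < 2L) {
      warning("comparison '", gname, "': fewer than 2 complete subject ",
              "pairs; skipped")
      next
    }
    if (sum(ok) < 5L) {
      warning("comparison '", gname, "': only ", sum(ok),
              " complete pairs; exact small-sample test")
    }
    wt <- suppressWarnings(
      stats::wilcox.test(mA[ok], mB[ok], paired = TRUE, exact = TRUE)
    )
    med_tab[[gname]] <- data.frame(
      comparison = gname, subject = subjects[ok],
      median_A = mA[ok], median_B = mB[ok], stringsAsFactors = FALSE
    )
    rows[[gname]] <- data.frame(
      comparison = gname, n_subjects = sum(ok),
      median_A = stats::median(mA[ok]), median_B = stats::median(mB[ok]),
      median_diff = stats::median(mA[ok] - mB[ok]),
      V = unname(wt$statistic), p = wt$p.value, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) stop("no comparison had enough complete pairs")
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  tests$significant <- tests$q < alpha
  structure(
    list(tests = tests, medians = do.call(rbind, med_tab), hubs = hubs,
         alpha = alpha),
    class = "rt_comparison"
  )
}

#' @export
print.rt_comparison <- function(x, ...) {
  cat("RT by hub (", x$hubs[1], " vs ", x$hubs[2],
      "), Wilcoxon signed-rank on per-subject medians:\n", sep = "")
  print(x$tests, digits = 4)
  invisible(x)
}

# Centered moving average with symmetric edge truncation: at position i the
# half-width shrinks to min(floor(w/2), i-1, n-i), so no zero-padding
# attenuates the extremes of the RT range.
moving_average_centered <- function(v, w) {
  n <- length(v)
  h <- max(0L, floor(w / 2))
  cs <- c(0, cumsum(v))
  k <- pmin(h, seq_len(n) - 1L, n - seq_len(n))
  lo <- seq_len(n) - k
  hi <- seq_len(n) + k
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' RT-sorted normalized out-degree dynamics
#'
#' Orders trials by ascending reaction time, stacks each region's
#' normalized outflow over that order, and smooths each trace with a
#' central moving average (window = `round(window_frac * n_trials)`,
#' minimum 1, step 1 trial, symmetric truncation at the edges). For the
#' first two named regions, a per-position paired Wilcoxon test on the raw
#' within-window trial values, Benjamini–Hochberg-adjusted across
#' positions, marks where the two traces differ.
#'
#' @param networks a [trial_networks()] result, or a list with `records`
#'   (needing `rt`) and `outflow`.
#' @param regions regions to report (first two are tested against each
#'   other); defaults to MCC and PCC.
#' @param window_frac moving-average window as a fraction of trials.
#' @param alpha threshold on adjusted p-values for `sig_mask`.
#' @param drop_discarded exclude tie-discarded trials?
#' @return An object of class `rt_curve`: `rt_grid` (sorted RTs), `curves`
#'   (positions x regions smoothed traces), `raw` (unsmoothed), `window`,
#'   `sig_mask`, `pvalues`, `qvalues`.
#' @export
rt_sorted_outdegree <- function(networks, regions = c("MCC", "PCC"),
                                window_frac = 0.10, alpha = 0.05,
                                drop_discarded = TRUE) {
  records <- networks$records
  outflow <- networks$outflow
  stopifnot(!is.null(records$rt), is.matrix(outflow),
            all(regions %in% colnames(outflow)))
  keep <- if (drop_discarded) records$hub != "discarded-tie" else
    rep(TRUE, nrow(records))
  if (!any(keep)) stop("all trials are tie-discarded; nothing to sort")
  rt <- records$rt[keep]
  of <- outflow[keep, regions, drop = FALSE]
  n <- length(rt)
  if (n < 20L) stop("need at least 20 usable trials, got ", n)
  ord <- order(rt)
  rt <- rt[ord]
  of <- of[ord, , drop = FALSE]
  w <- max(1L, round(window_frac * n))
  curves <- apply(of, 2L, moving_average_centered, w = w)
  pvals <- rep(NA_real_, n)
  if (length(regions) >= 2L) {
    h <- max(0L, floor(w / 2))
    a <- of[, 1L]; b <- of[, 2L]
    for (i in seq_len(n)) {
      k <- min(h, i - 1L, n - i)
      win <- (i - k):(i + k)
      d <- a[win] - b[win]
      if (length(d) < 3L || all(d == 0)) next
      pvals[i] <- suppressWarnings(
        stats::wilcox.test(d, exact = FALSE)$p.value
      )
    }
  }
  qvals <- stats::p.adjust(pvals, method = "BH")
  structure(
    list(rt_grid = rt, curves = curves, raw = of, window = w,
         sig_mask = !is.na(qvals) & qvals < alpha,
         pvalues = pvals, qvalues = qvals, regions = regions,
         alpha = alpha),
    class = "rt_curve"
  )
}

#' @export
print.rt_curve <- function(x, ...) {
  cat("RT-sorted out-degree curves over", length(x$rt_grid),
      "trials, window =", x$window, "trials\n")
  cat("  regions:", paste(x$regions, collapse = ", "),
      "; significant positions:", sum(x$sig_mask), "\n")
  invisible(x)
}
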