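#' Simulate one trial from a VAR specification
#'
#' Draws Gaussian innovations and iterates the autoregression, discarding an
#' initial burn-in so that the returned samples are (approximately) from the
#' stationary distribution. Identical `(spec, n_samples, seed, burn_in)`
#' yield identical output.
#'
#' @param spec a [var_spec()]; must be stationary.
#' @param n_samples number of retained samples (columns).
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @param burn_in samples generated and discarded before recording; default
#'   `10 * order * n_channels`.
#' @return numeric matrix, `n_channels x n_samples`, with channel labels as
#'   row names.
#' @export
simulate_var <- function(spec, n_samples, seed = NULL, burn_in = NULL) {
  stopifnot(inherits(spec, "var_spec"), is_count(n_samples))
  if (is.null(burn_in)) burn_in <- 10L * spec$order * spec$n_channels
  stopifnot(burn_in >= 0)
  sr <- spectral_radius(spec)
  if (sr >= 1) {
    stop("non-stationary specification: companion spectral radius ",
         format(sr, digits = 6), " >= 1")
  }
  with_seed(seed, simulate_var_core(spec, n_samples, burn_in))
}

# RNG-stream version used internally by the scenario builder (one stream
# per trial). Draw order: all innovations at once, column-major.
simulate_var_core <- function(spec, n_samples, burn_in) {
  n <- spec$n_channels
  p <- spec$order
  total <- n_samples + burn_in
  L <- chol(spec$noise_cov)               # upper triangular, Sigma = L'L
  eps <- t(L) %*% matrix(stats::rnorm(n * total), n, total)
  x <- matrix(0, n, total + p)            # p zero pre-samples
  A <- spec$coeffs
  for (t in seq_len(total)) {
    tt <- t + p
    acc <- eps[, t]
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% x[, tt - k]
    x[, tt] <- acc
  }
  out <- x[, (p + burn_in + 1L):(p + total), drop = FALSE]
  rownames(out) <- spec$labels
  out
}

#' Define a simulation scenario
#'
#' A scenario is a complete generative description of a pre-stimulus study:
#' a set of hub-regime VAR specifications, per-condition mixture
#' probabilities over those regimes, a per-regime reaction-time model,
#' trial/subject counts, and optional oscillatory components. Defaults
#' emulate the study design the pipeline targets: six sources at 250 Hz,
#' 1-s epochs, two feedback conditions (`"K+"` with vehicle-motion feedback,
#' `"K-"` without), a posterior-hub-leaning mixture under `"K+"` and a
#' midcingulate-leaning mixture under `"K-"`, and right-skewed lognormal
#' reaction times that are slower on posterior-hub (task-disengaged) trials.
#'
#' @param base_specs named list of [var_spec()] objects, one per hub regime.
#' @param regime_probs named list (one element per condition) of named
#'   probability vectors over the regimes; each must sum to 1.
#' @param rt_model named list (one element per regime) of lists
#'   `list(family = "lognormal", median = <s>, sdlog = <log-s scale>)`.
#' @param n_trials trials per condition per subject.
#' @param n_subjects number of subjects.
#' @param epoch_len samples per trial (must be at least `10 * order`).
#' @param fs sampling rate in Hz.
#' @param osc_components optional list of oscillatory components, each
#'   `list(channel =, freq =, amplitude =, rt_slope = 0, regime = NULL)`:
#'   a sinusoid with uniform random per-trial phase added to `channel`, with
#'   amplitude `amplitude + rt_slope * rt`, restricted to trials of `regime`
#'   when given.
#' @param seed master integer seed for [build_scenario()].
#' @return An object of class `scenario`.
#' @export
scenario <- function(base_specs = NULL, regime_probs = NULL, rt_model = NULL,
                     n_trials = 200L, n_subjects = 10L, epoch_len = 250L,
                     fs = 250, osc_components = NULL, seed = 1L) {
  if (is.null(base_specs)) {
    base_specs <- list("MCC-hub" = hub_var_spec("MCC-hub"),
                       "PCC-hub" = hub_var_spec("PCC-hub"),
                       "null"    = hub_var_spec("null"))
  }
  if (is.null(regime_probs)) {
    regime_probs <- list(
      "K+" = c("MCC-hub" = 0.255, "PCC-hub" = 0.319, "null" = 0.426),
      "K-" = c("MCC-hub" = 0.349, "PCC-hub" = 0.231, "null" = 0.420)
    )
  }
  if (is.null(rt_model)) {
    rt_model <- list(
      "MCC-hub" = list(family = "lognormal", median = 1.0, sdlog = 0.3),
      "PCC-hub" = list(family = "lognormal", median = 1.3, sdlog = 0.3),
      "null"    = list(family = "lognormal", median = 1.15, sdlog = 0.3)
    )
  }
  stopifnot(is.list(base_specs), length(names(base_specs)) > 0,
            is.list(regime_probs), is.list(rt_model),
            is_count(n_trials), is_count(n_subjects), is_count(epoch_len),
            fs > 0)
  labels0 <- base_specs[[1L]]$labels
  for (nm in names(base_specs)) {
    sp <- base_specs[[nm]]
    stopifnot(inherits(sp, "var_spec"))
    if (!identical(sp$labels, labels0)) {
      stop("all regime specifications must share channel labels")
    }
    if (epoch_len < 10L * sp$order) {
      stop("epoch_len must be >= 10 * order for regime '", nm, "'")
    }
  }
  for (cond in names(regime_probs)) {
    pr <- regime_probs[[cond]]
    unknown <- setdiff(names(pr), names(base_specs))
    if (length(unknown)) {
      stop("unknown regime name(s) in regime_probs[['", cond, "']]: ",
           paste(unknown, collapse = ", "))
    }
    if (abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
      stop("regime_probs[['", cond, "']] must be non-negative and sum to 1")
    }
  }
  for (nm in names(rt_model)) {
    m <- rt_model[[nm]]
    if (!identical(m$family %||% "lognormal", "lognormal")) {
      stop("unsupported RT family '", m$family, "' (lognormal supported)")
    }
    stopifnot(m$median > 0, m$sdlog >= 0)
  }
  missing_rt <- setdiff(names(base_specs), names(rt_model))
  if (length(missing_rt)) {
    stop("rt_model missing for regime(s): ", paste(missing_rt, collapse = ", "))
  }
  if (!is.null(osc_components)) {
    for (oc in osc_components) {
      stopifnot(oc$channel %in% labels0, oc$freq > 0, oc$freq < fs / 2)
    }
  }
  structure(
    list(base_specs = base_specs, regime_probs = regime_probs,
         rt_model = rt_model, n_trials = as.integer(n_trials),
         n_subjects = as.integer(n_subjects),
         epoch_len = as.integer(epoch_len), fs = fs,
         osc_components = osc_components, seed = as.integer(seed)),
    class = "scenario"
  )
}

draw_rt <- function(model) {
  stats::rlnorm(1L, meanlog = log(model$median), sdlog = model$sdlog)
}

# Generate one trial from its recorded per-trial seed: VAR innovations,
# then RT, then one uniform phase per applicable oscillatory component.
# This fixed draw order is what makes trials reproducible in isolation.
simulate_trial <- function(scn, regime, trial_seed) {
  spec <- scn$base_specs[[regime]]
  with_seed(trial_seed, {
    x <- simulate_var_core(spec, scn$epoch_len,
                           burn_in = 10L * spec$order * spec$n_channels)
    rt <- draw_rt(scn$rt_model[[regime]])
    if (!is.null(scn$osc_components)) {
      tgrid <- (seq_len(scn$epoch_len) - 1L) / scn$fs
      for (oc in scn$osc_components) {
        if (!is.null(oc$regime) && !identical(oc$regime, regime)) next
        amp <- oc$amplitude + (oc$rt_slope %||% 0) * rt
        phase <- stats::runif(1L, 0, 2 * pi)
        i <- match(oc$channel, spec$labels)
        x[i, ] <- x[i, ] + amp * sin(2 * pi * oc$freq * tgrid + phase)
      }
    }
    list(data = x, rt = rt)
  })
}

#' Build a trial-structured epoch set from a scenario
#'
#' For every subject, condition and trial: draw a hub regime from the
#' condition's mixture, simulate the trial from that regime's VAR
#' specification, draw its reaction time from the regime's RT model, and
#' record the ground-truth regime plus the per-trial seed (so any trial can
#' be re-simulated in isolation). Deterministic under the scenario seed.
#'
#' @param scn a [scenario()].
#' @return An [epoch_set()] whose `meta` includes `regime_truth` and
#'   `trial_seed`.
#' @export
build_scenario <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  conds <- names(scn$regime_probs)
  n_total <- scn$n_subjects * length(conds) * scn$n_trials
  # Master stream: regime draws and per-trial seeds, in trial order.
  plan <- with_seed(scn$seed, {
    subj <- character(0); cond <- character(0); regime <- character(0)
    tseed <- integer(0)
    for (s in seq_len(scn$n_subjects)) {
      for (cd in conds) {
        pr <- scn$regime_probs[[cd]]
        reg <- sample(names(pr), scn$n_trials, replace = TRUE, prob = pr)
        sd <- sample.int(.Machine$integer.max - 1L, scn$n_trials)
        subj <- c(subj, rep(sprintf("S%02d", s), scn$n_trials))
        cond <- c(cond, rep(cd, scn$n_trials))
        regime <- c(regime, reg)
        tseed <- c(tseed, sd)
      }
    }
    data.frame(subject = subj, condition = cond, regime_truth = regime,
               trial_seed = tseed, stringsAsFactors = FALSE)
  })
  trials <- vector("list", n_total)
  rt <- numeric(n_total)
  for (k in seq_len(n_total)) {
    tr <- simulate_trial(scn, plan$regime_truth[k], plan$trial_seed[k])
    trials[[k]] <- tr$data
    rt[k] <- tr$rt
  }
  meta <- data.frame(trial = seq_len(n_total), rt = rt,
                     condition = plan$condition, subject = plan$subject,
                     regime_truth = plan$regime_truth,
                     trial_seed = plan$trial_seed,
                     stringsAsFactors = FALSE)
  epoch_set(trials, meta, fs = scn$fs,
            labels = scn$base_specs[[1L]]$labels)
}

#' Add a fixed-frequency oscillation to one channel of every trial
#'
#' Adds `amplitude * sin(2*pi*freq*t + phi)` to the named channel, with an
#' independent uniform random phase `phi` per trial (random phase avoids
#' phase-locked artifacts when spectra are averaged across trials). All
#' other channels are untouched.
#'
#' @param epochs an [epoch_set()].
#' @param channel channel label.
#' @param freq oscillation frequency in Hz; must be below Nyquist (`fs/2`).
#' @param amplitude sinusoid amplitude in signal units (adds `amplitude^2/2`
#'   to the channel variance on average).
#' @param seed integer seed for the per-trial phases.
#' @return The modified `epoch_set`.
#' @export
add_oscillation <- function(epochs, channel, freq, amplitude, seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (freq <= 0 || freq >= epochs$fs / 2) {
    stop("freq must lie in (0, fs/2) = (0, ", epochs$fs / 2, ")")
  }
  i <- match(channel, epochs$labels)
  if (is.na(i)) stop("unknown channel '", channel, "'")
  n_trials <- length(epochs$trials)
  phases <- with_seed(seed, stats::runif(n_trials, 0, 2 * pi))
  tgrid <- (seq_len(ncol(epochs$trials[[1L]])) - 1L) / epochs$fs
  for (k in seq_len(n_trials)) {
    epochs$trials[[k]][i, ] <- epochs$trials[[k]][i, ] +
      amplitude * sin(2 * pi * freq * tgrid + phases[k])
  }
  epochs
}
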