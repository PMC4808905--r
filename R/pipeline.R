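#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults are the
#' procedure constants of the target study design: 2000 surrogates and
#' FDR-adjusted alpha 0.01 at session level, a 10% moving-average window,
#' 0.9 group consensus; the per-trial stage (not specified by the study)
#' defaults to 200 surrogates at alpha 0.05 for tractability.
#'
#' @param scenario a [scenario()] to simulate, or `NULL` when reading
#'   epochs from disk.
#' @param epochs_path directory readable by [read_epochs()] (used when
#'   `scenario` is `NULL`).
#' @param p_max upper bound for BIC order selection.
#' @param n_surrogates session-level surrogate count.
#' @param session_alpha session-level FDR-adjusted threshold.
#' @param trial_surrogates,trial_alpha per-trial surrogate count and
#'   threshold.
#' @param window_frac RT-sorted moving-average window fraction.
#' @param consensus group consensus proportion for P(edge).
#' @param hubs the two hub regions compared in trial-level statistics.
#' @param spectral_channels channels whose RT-sorted spectra are computed.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param out_dir output directory for [run_pipeline()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, epochs_path = NULL, p_max = 6L,
                       n_surrogates = 2000L, session_alpha = 0.01,
                       trial_surrogates = 200L, trial_alpha = 0.05,
                       window_frac = 0.10, consensus = 0.9,
                       hubs = c("MCC", "PCC"),
                       spectral_channels = c("MCC", "PCC"),
                       seed = 1L, out_dir = "gcflow-results") {
  stopifnot(session_alpha > 0, session_alpha < 1,
            trial_alpha > 0, trial_alpha < 1,
            window_frac > 0, window_frac < 1,
            consensus > 0, consensus <= 1,
            is_count(p_max), is_count(n_surrogates),
            is_count(trial_surrogates))
  if (is.null(scenario) && is.null(epochs_path)) {
    stop("provide either a scenario or an epochs_path")
  }
  if (!is.null(epochs_path) && !file.exists(file.path(epochs_path,
                                                      "manifest.json"))) {
    stop("epochs_path is not a readable epoch directory: ", epochs_path)
  }
  structure(
    list(scenario = scenario, epochs_path = epochs_path,
         p_max = as.integer(p_max), n_surrogates = as.integer(n_surrogates),
         session_alpha = session_alpha,
         trial_surrogates = as.integer(trial_surrogates),
         trial_alpha = trial_alpha, window_frac = window_frac,
         consensus = consensus, hubs = hubs,
         spectral_channels = spectral_channels, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a scenario description from a YAML or JSON file
#'
#' The file mirrors the [scenario()] arguments; VAR specifications are
#' given either as a shipped template reference
#' (`template: "PCC-hub"`, optional `coupling`, `self_lag1`, `self_lag2`,
#' `noise_sd`) or as explicit `coeffs` (list of square matrices) plus
#' optional `noise_cov` and `labels`.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return A [scenario()].
#' @export
scenario_from_file <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported scenario file type: ", path)
  }
  parse_spec <- function(s) {
    if (!is.null(s$template)) {
      do.call(hub_var_spec, s[intersect(names(s),
        c("template", "coupling", "self_lag1", "self_lag2", "noise_sd"))])
    } else {
      coeffs <- lapply(s$coeffs, function(A) {
        m <- do.call(rbind, lapply(A, as.numeric))
        dimnames(m) <- NULL
        m
      })
      nc <- if (!is.null(s$noise_cov)) {
        do.call(rbind, lapply(s$noise_cov, as.numeric))
      } else NULL
      var_spec(coeffs, noise_cov = nc, labels = s$labels)
    }
  }
  base_specs <- lapply(cfg$base_specs, parse_spec)
  regime_probs <- lapply(cfg$regime_probs, function(pr) unlist(pr))
  args <- list(base_specs = base_specs, regime_probs = regime_probs,
               rt_model = cfg$rt_model)
  for (f in c("n_trials", "n_subjects", "epoch_len", "fs", "seed")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  if (!is.null(cfg$osc_components)) args$osc_components <- cfg$osc_components
  do.call(scenario, args)
}

edge_list_df <- function(values, pvals, qvals, adjacency, labels) {
  n <- length(labels)
  idx <- which(row(values) != col(values))
  data.frame(
    source = labels[col(values)[idx]], target = labels[row(values)[idx]],
    magnitude = values[idx], p = pvals[idx], q = qvals[idx],
    significant = adjacency[idx], stringsAsFactors = FALSE
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate (or read) epochs; per session
#' (subject x condition) preprocess, select the model order by BIC on the
#' pooled trials, fit and validate the MVAR model, and test edge
#' significance against the phase-randomization null; at group level
#' compute P(edge), the consensus network, and paired McNemar condition
#' comparisons; at trial level classify causal hubs, tabulate hub
#' percentages with the 2x2 repeated-measures ANOVA, compare RTs between
#' hub-dominated trials, trace RT-sorted normalized out-degree, and build
#' RT-sorted baseline-subtracted spectral images. All tables are written
#' as TSV under `config$out_dir` plus a `summary.json` with seeds,
#' parameters and per-stage status; outputs are byte-identical across
#' reruns with the same config.
#'
#' A stage failure is recorded in the summary and the stages depending on
#' it are skipped with an explanation; independent stages still run.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory results and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "sessions"), showWarnings = FALSE)
  dir.create(file.path(out, "group"), showWarnings = FALSE)
  dir.create(file.path(out, "trials"), showWarnings = FALSE)
  dir.create(file.path(out, "spectra"), showWarnings = FALSE)
  status <- list()
  results <- list()
  fail <- function(stage, e) {
    status[[stage]] <<- paste("failed:", conditionMessage(e))
  }

  # -- data ---------------------------------------------------------------
  epochs <- tryCatch({
    ep <- if (!is.null(config$scenario)) {
      scn <- config$scenario
      scn$seed <- config$seed
      build_scenario(scn)
    } else {
      read_epochs(config$epochs_path)
    }
    status$data <- "ok"
    ep
  }, error = function(e) { fail("data", e); NULL })
  if (is.null(epochs)) {
    status <- c(status, list(sessions = "skipped: no data",
                             group = "skipped: no data",
                             trials = "skipped: no data",
                             spectra = "skipped: no data"))
    summary_json(config, status, out)
    return(invisible(list(status = status)))
  }
  results$epochs <- epochs

  sessions <- split(seq_along(epochs$trials),
                    list(subject = epochs$meta$subject,
                         condition = epochs$meta$condition), sep = "|")
  sessions <- sessions[vapply(sessions, length, 0L) > 0L]
  seeds <- derive_seeds(config$seed, length(sessions) + 2L)
  session_seeds <- seeds[seq_along(sessions)]
  trial_seed <- seeds[length(sessions) + 1L]

  # -- session level ------------------------------------------------------
  session_res <- tryCatch({
    res <- list()
    for (si in seq_along(sessions)) {
      key <- names(sessions)[si]
      idx <- sessions[[si]]
      trials <- lapply(epochs$trials[idx], preprocess_epoch)
      sel <- select_order_bic(trials, config$p_max)
      fit <- fit_mvar(trials, sel$order, labels = epochs$labels)
      val <- validate_model(fit, trials)
      eg <- edge_significance(trials, sel$order,
                              n_surrogates = config$n_surrogates,
                              alpha = config$session_alpha,
                              seed = session_seeds[si])
      sdir <- file.path(out, "sessions", safe_name(key))
      dir.create(sdir, showWarnings = FALSE)
      write_tsv(data.frame(
        metric = c("order", "n_obs", "whiteness_overall_p",
                   "consistency_pct", "spectral_radius", "stable"),
        value = c(sel$order, fit$n_obs, val$whiteness_overall,
                  val$consistency_pct, val$spectral_radius,
                  as.integer(val$stable))
      ), file.path(sdir, "validation.tsv"))
      gm <- as.data.frame(eg$gc$values)
      write_tsv(cbind(target = epochs$labels, gm),
                file.path(sdir, "gc_matrix.tsv"))
      write_tsv(edge_list_df(eg$gc$values, eg$pvalues, eg$qvalues,
                             eg$adjacency, epochs$labels),
                file.path(sdir, "edges.tsv"))
      res[[key]] <- list(order = sel$order, fit = fit, validation = val,
                         graph = eg)
    }
    status$sessions <- "ok"
    res
  }, error = function(e) { fail("sessions", e); NULL })
  results$sessions <- session_res

  # -- group level --------------------------------------------------------
  if (is.null(session_res)) {
    status$group <- "skipped: session stage failed"
  } else {
    tryCatch({
      conds <- unique(epochs$meta$condition)
      subj_of <- sub("\\|.*$", "", names(session_res))
      cond_of <- sub("^.*\\|", "", names(session_res))
      group <- list()
      for (cd in conds) {
        gl <- lapply(which(cond_of == cd), function(i) {
          session_res[[i]]$graph
        })
        gp <- group_edge_proportion(gl, threshold = config$consensus)
        group[[cd]] <- gp
        pe <- as.data.frame(gp$p_edge)
        write_tsv(cbind(target = epochs$labels, pe),
                  file.path(out, "group",
                            paste0("p_edge_", safe_name(cd), ".tsv")))
        cons <- which(gp$consensus, arr.ind = TRUE)
        write_tsv(data.frame(source = epochs$labels[cons[, 2L]],
                             target = epochs$labels[cons[, 1L]],
                             p_edge = gp$p_edge[cons]),
                  file.path(out, "group",
                            paste0("consensus_", safe_name(cd), ".tsv")))
      }
      if (length(conds) == 2L) {
        sA <- sort(names(session_res)[cond_of == conds[1L]])
        sB <- sort(names(session_res)[cond_of == conds[2L]])
        pairs <- intersect(sub("\\|.*$", "", sA), sub("\\|.*$", "", sB))
        gA <- lapply(pairs, function(s) {
          session_res[[paste(s, conds[1L], sep = "|")]]$graph
        })
        gB <- lapply(pairs, function(s) {
          session_res[[paste(s, conds[2L], sep = "|")]]$graph
        })
        mc <- mcnemar_condition_test(gA, gB)
        group$mcnemar <- mc
        write_tsv(mc$edges, file.path(out, "group", "mcnemar.tsv"))
      }
      results$group <- group
      status$group <- "ok"
    }, error = function(e) fail("group", e))
  }

  # -- trial level --------------------------------------------------------
  trial_res <- NULL
  if (is.null(session_res)) {
    status$trials <- "skipped: session stage failed"
  } else {
    tryCatch({
      orders <- vapply(session_res, `[[`, 0L, "order")
      p_common <- as.integer(stats::median(orders))  # shared across trials
      tn <- trial_networks(epochs, p_common,
                           n_surrogates = config$trial_surrogates,
                           alpha = config$trial_alpha, seed = trial_seed)
      write_tsv(cbind(tn$records, as.data.frame(tn$outflow)),
                file.path(out, "trials", "hub_table.tsv"))
      an <- hub_percentage_anova(tn$records, hubs = config$hubs)
      write_tsv(data.frame(
        metric = c("interaction_F", "interaction_p", "df1", "df2",
                   paste0("mean_", colnames(an$table))),
        value = c(an$F, an$p, an$df, unname(an$cell_means))
      ), file.path(out, "trials", "anova.tsv"))
      rtc <- rt_by_hub_comparison(tn$records, hubs = config$hubs)
      write_tsv(rtc$tests, file.path(out, "trials", "rt_comparison.tsv"))
      for (cd in unique(tn$records$condition)) {
        sel <- tn$records$condition == cd
        curve <- rt_sorted_outdegree(
          list(records = tn$records[sel, ], outflow = tn$outflow[sel, ,
                                                                 drop = FALSE]),
          regions = config$hubs, window_frac = config$window_frac
        )
        write_tsv(cbind(data.frame(rt = curve$rt_grid),
                        as.data.frame(curve$curves),
                        sig = curve$sig_mask),
                  file.path(out, "trials",
                            paste0("rt_curves_", safe_name(cd), ".tsv")))
      }
      trial_res <- list(networks = tn, anova = an, rt = rtc)
      results$trials <- trial_res
      status$trials <- "ok"
    }, error = function(e) fail("trials", e))
  }

  # -- spectra ------------------------------------------------------------
  tryCatch({
    for (cd in unique(epochs$meta$condition)) {
      sel <- which(epochs$meta$condition == cd)
      for (ch in config$spectral_channels) {
        ci <- match(ch, epochs$labels)
        acts <- lapply(epochs$trials[sel], function(m) m[ci, ])
        img <- rt_sorted_spectrogram(acts, epochs$meta$rt[sel],
                                     fs = epochs$fs)
        df <- as.data.frame(img$values)
        colnames(df) <- sprintf("f%.2f", img$freq)
        write_tsv(cbind(data.frame(rt = img$rt), df),
                  file.path(out, "spectra",
                            paste0(safe_name(cd), "_", safe_name(ch),
                                   ".tsv")))
      }
    }
    status$spectra <- "ok"
  }, error = function(e) fail("spectra", e))

  results$status <- status
  summary_json(config, status, out,
               orders = if (!is.null(session_res)) {
                 vapply(session_res, `[[`, 0L, "order")
               } else NULL)
  invisible(results)
}

summary_json <- function(config, status, out, orders = NULL) {
  summ <- list(
    package = "gcflow",
    version = as.character(utils::packageVersion("gcflow")),
    seed = config$seed,
    parameters = list(
      p_max = config$p_max, n_surrogates = config$n_surrogates,
      session_alpha = config$session_alpha,
      trial_surrogates = config$trial_surrogates,
      trial_alpha = config$trial_alpha,
      window_frac = config$window_frac, consensus = config$consensus,
      hubs = config$hubs, spectral_channels = config$spectral_channels
    ),
    selected_orders = as.list(orders),
    stages = status
  )
  jsonlite::write_json(summ, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
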