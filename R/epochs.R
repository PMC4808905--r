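#' Trial-structured multichannel epochs
#'
#' The pipeline's universal input container: a list of fixed-size
#' `channels x samples` matrices plus per-trial metadata (reaction time,
#' condition, subject, and — for simulated data — the ground-truth regime
#' and per-trial seed).
#'
#' @param trials list of numeric `channels x samples` matrices, all the
#'   same shape.
#' @param meta data frame with one row per trial; must contain `rt`
#'   (seconds, positive), `condition` and `subject`.
#' @param fs sampling rate in Hz.
#' @param labels unique channel names, length = channel count.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(trials, meta, fs, labels) {
  stopifnot(is.list(trials), length(trials) >= 1L, is.data.frame(meta),
            nrow(meta) == length(trials), fs > 0)
  d <- dim(trials[[1L]])
  for (k in seq_along(trials)) {
    if (!is.matrix(trials[[k]]) || !identical(dim(trials[[k]]), d)) {
      stop("trial ", k, " does not match the common channels x samples shape")
    }
  }
  stopifnot(length(labels) == d[1L], !anyDuplicated(labels))
  req <- c("rt", "condition", "subject")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols)) {
    stop("meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(meta$rt <= 0)) stop("all reaction times must be positive")
  if (is.null(meta$trial)) meta$trial <- seq_len(nrow(meta))
  structure(
    list(trials = trials, meta = meta, fs = fs,
         labels = as.character(labels)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$trials[[1L]])
  cat("epoch_set:", length(x$trials), "trials of", d[1L], "channels x",
      d[2L], "samples @", x$fs, "Hz\n")
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  cat("  subjects:", length(unique(x$meta$subject)),
      " conditions:", paste(unique(x$meta$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an epoch set by trial index or metadata predicate
#'
#' @param epochs an [epoch_set()].
#' @param idx integer or logical index over trials.
#' @return The reduced `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- seq_along(epochs$trials)[idx]
  if (length(keep) == 0L) stop("subset selects no trials")
  meta <- epochs$meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  epoch_set(epochs$trials[keep], meta, epochs$fs, epochs$labels)
}

#' Write / read an epoch set as a plain-text directory
#'
#' The on-disk dialect is a directory holding `manifest.json` (sampling
#' rate, channel labels, and the per-trial metadata including each trial's
#' matrix file name) plus one tab-delimited matrix per trial with
#' rows = channels and columns = samples. The round trip is lossless to
#' full double precision, and trial order is restored from the manifest
#' regardless of file-name order on disk.
#'
#' @param epochs an [epoch_set()].
#' @param path directory to create/read.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns the reconstructed [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("trial_%04d.tsv", seq_along(epochs$trials))
  for (k in seq_along(epochs$trials)) {
    utils::write.table(
      format(epochs$trials[[k]], digits = 17, scientific = TRUE,
             trim = TRUE),
      file.path(path, files[k]),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  meta <- epochs$meta
  meta$file <- files
  manifest <- list(
    format = "gcflow-epochs-v1",
    fs = epochs$fs,
    labels = epochs$labels,
    n_channels = length(epochs$labels),
    n_samples = ncol(epochs$trials[[1L]]),
    trials = meta
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in c("fs", "labels", "n_channels", "n_samples", "trials")) {
    if (is.null(manifest[[f]])) stop("manifest lacks field '", f, "'")
  }
  meta <- as.data.frame(manifest$trials)
  ord <- order(meta$trial)
  meta <- meta[ord, , drop = FALSE]          # order from manifest indices
  trials <- vector("list", nrow(meta))
  for (k in seq_len(nrow(meta))) {
    m <- as.matrix(utils::read.table(file.path(path, meta$file[k]),
                                     sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != manifest$n_channels || ncol(m) != manifest$n_samples) {
      stop("trial ", meta$trial[k], " (", meta$file[k], "): matrix is ",
           nrow(m), " x ", ncol(m), " but manifest declares ",
           manifest$n_channels, " x ", manifest$n_samples)
    }
    rownames(m) <- manifest$labels
    trials[[k]] <- m
  }
  meta$file <- NULL
  rownames(meta) <- NULL
  epoch_set(trials, meta, fs = as.numeric(manifest$fs),
            labels = manifest$labels)
}
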