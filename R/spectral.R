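hann_window <- function(n) {
  # symmetric Hann taper without zero endpoints (MATLAB hanning convention)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

#' Welch log-power spectral density of a single-channel epoch
#'
#' Splits the epoch into overlapping Hann-windowed segments (default
#' 128 samples, 50% overlap), zero-pads each to `nfft` (default 256)
#' points, averages the one-sided periodograms, and reports the result in
#' dB (`10 * log10` of the power spectral density). With the defaults at
#' 250 Hz the bin spacing is 250/256 ~ 0.977 Hz; all bins whose centers
#' fall in the reported band (default 0.98–30.3 Hz, compared at two-decimal
#' precision, giving 31 bins) are returned.
#'
#' @param x numeric vector, one channel of one epoch; must contain at
#'   least `seg_len` samples (a full 1-s epoch at 250 Hz has 250).
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples.
#' @param overlap fractional segment overlap.
#' @param nfft FFT length after zero-padding (>= `seg_len`).
#' @param band reported frequency band `c(lo, hi)` in Hz.
#' @return An object of class `welch_psd`: `freq` (bin centers, Hz), `db`
#'   (log power, dB), `psd` (linear density, signal-units^2/Hz),
#'   `n_segments`.
#' @export
welch_log_psd <- function(x, fs = 250, seg_len = 128L, overlap = 0.5,
                          nfft = 256L, band = c(0.98, 30.3)) {
  x <- as.numeric(x)
  T <- length(x)
  if (T < seg_len) {
    stop("epoch has ", T, " samples; need at least one full segment (",
         seg_len, ")")
  }
  stopifnot(nfft >= seg_len, overlap >= 0, overlap < 1)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq.int(1L, T - seg_len + 1L, by = step)
  w <- hann_window(seg_len)
  scale <- 1 / (fs * sum(w^2))
  nb <- nfft %/% 2L + 1L
  acc <- numeric(nb)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - seg_len)))
    acc <- acc + Mod(X[seq_len(nb)])^2
  }
  psd <- acc / length(starts) * scale
  psd[2:(nb - 1L)] <- 2 * psd[2:(nb - 1L)]     # one-sided
  freq <- (seq_len(nb) - 1L) * fs / nfft
  inband <- round(freq, 2) >= band[1L] & round(freq, 2) <= band[2L]
  structure(
    list(freq = freq[inband], db = 10 * log10(psd[inband]),
         psd = psd[inband], n_segments = length(starts),
         fs = fs, band = band),
    class = "welch_psd"
  )
}

#' RT-sorted, baseline-subtracted spectral image
#'
#' Computes the Welch log-power spectrum of one channel for every trial,
#' orders the rows by ascending reaction time, and subtracts the reference
#' spectrum: the mean dB spectrum of the trials whose RT lies strictly
#' below the 10th percentile of RTs (performance baseline). If no trial
#' falls strictly below that value (massive ties), the single fastest
#' trial is used, with a warning.
#'
#' @param activations list (or matrix with trials in rows) of
#'   single-channel epochs, one per trial.
#' @param rts positive reaction times, one per trial (>= 10 trials so the
#'   bottom decile is non-empty).
#' @param ... passed to [welch_log_psd()].
#' @return An object of class `spectral_image`: `freq`, `values`
#'   (trials x bins, dB relative to baseline, rows RT-ascending), `rt`
#'   (sorted), `baseline` (dB), `baseline_rows` (row indices, within the
#'   sorted image, that formed the baseline).
#' @export
rt_sorted_spectrogram <- function(activations, rts, ...) {
  if (is.matrix(activations)) {
    activations <- lapply(seq_len(nrow(activations)),
                          function(i) activations[i, ])
  }
  stopifnot(length(activations) == length(rts), length(rts) >= 10L,
            all(rts > 0))
  ord <- order(rts)
  rts <- rts[ord]
  activations <- activations[ord]
  spectra <- lapply(activations, welch_log_psd, ...)
  freq <- spectra[[1L]]$freq
  mat <- do.call(rbind, lapply(spectra, `[[`, "db"))
  q10 <- stats::quantile(rts, 0.10, names = FALSE)
  base_rows <- which(rts < q10)
  if (length(base_rows) == 0L) {
    warning("no trial strictly below the 10th-percentile RT; using the ",
            "single fastest trial as baseline")
    base_rows <- 1L
  }
  baseline <- colMeans(mat[base_rows, , drop = FALSE])
  values <- sweep(mat, 2L, baseline)
  structure(
    list(freq = freq, values = values, rt = rts, baseline = baseline,
         baseline_rows = base_rows),
    class = "spectral_image"
  )
}

#' @export
print.spectral_image <- function(x, ...) {
  cat("RT-sorted spectral image:", nrow(x$values), "trials x",
      length(x$freq), "bins (",
      format(min(x$freq), digits = 3), "-",
      format(max(x$freq), digits = 4), "Hz ), baseline from",
      length(x$baseline_rows), "bottom-decile trials\n")
  invisible(x)
}
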