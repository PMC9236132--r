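# Forward-backward application of an FIR filter equals one pass of the
# zero-phase kernel conv(b, rev(b)) (response |B|^2). Kernels of a filter
# cascade are combined by convolution and applied once per channel via
# FFT convolution, with odd-reflection padding so edge transients are
# absorbed in the discarded pad rather than the data.
zero_phase_kernel <- function(b) {
  b <- as.numeric(b)
  k <- stats::convolve(b, b, type = "open")  # rev() immaterial: autocorrelation
  k
}

combine_kernels <- function(k1, k2) stats::convolve(k1, rev(k2), type = "open")

apply_zero_phase <- function(x, k) {
  n <- length(x)
  half <- (length(k) - 1L) %/% 2L
  pad <- min(half + 1L, n - 1L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- stats::convolve(xp, rev(k), type = "open")
  y[(pad + half + 1):(pad + half + n)]
}

# Windowed-sinc (Hamming) FIR order for ~40 dB stop-band at transition width tw.
fir_order <- function(fs, tw) {
  n <- ceiling(3.3 * fs / tw)
  n + (n %% 2L)  # even order so high-pass/stop designs keep a passband at Nyquist
}

#' Filter and re-reference a recording
#'
#' Applies, in order: a band-stop filter around the mains frequency, an FIR
#' high-pass (removes DC and drift), an FIR low-pass (removes high-frequency
#' artifacts), then an average reference (each channel minus the instantaneous
#' mean of all channels). All filters are windowed-sinc FIR applied
#' forward-backward, so the pass is zero-phase with no group delay.
#'
#' @param rec An [eeg_recording()].
#' @param line_freq Mains frequency in Hz, or `NULL` to skip the band-stop.
#'   Default 50 Hz.
#' @param hp High-pass edge in Hz (default 1).
#' @param lp Low-pass edge in Hz (default 50).
#' @param notch_halfwidth Half-width of the band-stop in Hz (default 2, i.e.
#'   a 50 +/- 2 Hz stop band).
#' @param artifact_remover Optional pass-through hook for ocular/muscle
#'   artifact removal (e.g. an external ICA implementation): a function
#'   `(matrix, fs, channel_labels) -> matrix` applied after filtering and
#'   before re-referencing. `NULL` (the default) skips the step; synthetic
#'   cohorts are generated artifact-free.
#' @return A filtered, re-referenced `eeg_recording`.
#' @export
preprocess_recording <- function(rec, line_freq = 50, hp = 1, lp = 50,
                                 notch_halfwidth = 2, artifact_remover = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (hp >= lp) stop("high-pass edge must be below the low-pass edge")
  if (hp <= 0 || lp >= fs / 2) stop("band edges must lie inside (0, fs/2)")
  if (nrow(rec$data) < 2)
    stop("average re-referencing refused for a single-channel recording ",
         "(it would zero the data)")
  nyq <- fs / 2
  x <- rec$data - rowMeans(rec$data)  # exact DC removal; the FIR high-pass
                                      # handles drift, within design ripple
  b_hp <- signal::fir1(fir_order(fs, hp), hp / nyq, type = "high")
  b_lp <- signal::fir1(fir_order(fs, 5), lp / nyq, type = "low")
  k <- combine_kernels(zero_phase_kernel(b_hp), zero_phase_kernel(b_lp))
  if (!is.null(line_freq)) {
    if (line_freq <= hp || line_freq >= nyq)
      stop("`line_freq` must lie inside the analysis band")
    b_stop <- signal::fir1(fir_order(fs, 1),
                           c(line_freq - notch_halfwidth,
                             min(line_freq + notch_halfwidth, nyq * 0.999)) / nyq,
                           type = "stop")
    k <- combine_kernels(zero_phase_kernel(b_stop), k)
  }
  x <- t(apply(x, 1, function(ch) apply_zero_phase(ch, k)))
  if (!is.null(artifact_remover)) {
    x <- artifact_remover(x, fs, rec$channel_labels)
    if (!is.matrix(x) || nrow(x) != length(rec$channel_labels))
      stop("`artifact_remover` must return a matrix with one row per channel")
  }
  # average reference: subtract the instantaneous mean over channels
  x <- sweep(x, 2, colMeans(x))
  out <- rec
  out$data <- x
  rownames(out$data) <- rec$channel_labels
  out$meta$preprocessed <- list(line_freq = line_freq, hp = hp, lp = lp)
  out
}

#' Split a recording into consecutive non-overlapping epochs
#'
#' Epochs tile the recording as half-open sample intervals
#' `[k*L, (k+1)*L)` with `L = round(epoch_length * fs)`; a trailing partial
#' window is discarded.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_length Epoch length in seconds (default 4).
#' @return An `epoch_set`: list of channels-by-L matrices plus metadata.
#' @export
epoch_signal <- function(rec, epoch_length = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- round(epoch_length * rec$fs)
  n <- ncol(rec$data)
  k <- n %/% L
  if (k < 1) stop("recording shorter than one epoch (", epoch_length, " s)")
  epochs <- lapply(seq_len(k) - 1L, function(i) {
    rec$data[, (i * L + 1):((i + 1) * L), drop = FALSE]
  })
  structure(list(epochs = epochs, epoch_length = epoch_length, fs = rec$fs,
                 channel_labels = rec$channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s (%d channels @ %g Hz)\n",
              length(x$epochs), x$epoch_length, length(x$channel_labels), x$fs))
  invisible(x)
}
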