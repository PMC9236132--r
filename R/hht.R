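#' EEG rhythm band edges
#'
#' The five conventional rhythms with the band edges used throughout the
#' pipeline (values in Hz).
#'
#' @return A data.frame with columns `rhythm`, `lo`, `hi`.
#' @export
rhythm_bands <- function() {
  data.frame(rhythm = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0, 3.9, 7.8, 13.7, 29.3),
             hi = c(3.9, 7.8, 13.7, 29.3, 46.9))
}

#' Empirical mode decomposition
#'
#' Sifts a series into intrinsic mode functions (IMFs) using cubic-spline
#' envelopes of the local extrema, with mirrored boundary extrema so short
#' epochs do not suffer envelope collapse at the edges. Sifting stops per IMF
#' when the Cauchy-type standard-deviation criterion between successive sifts
#' falls below `sd_tol` or after `max_sift` sifts; decomposition stops when
#' the residual has fewer than two maxima/minima or `max_imfs` is reached.
#'
#' @param x Numeric series (length >= 8, finite).
#' @param fs Sampling rate in Hz.
#' @param max_imfs Maximum number of IMFs (default 12).
#' @param max_sift Maximum sifts per IMF (default 10).
#' @param sd_tol Sifting stop threshold (default 0.2).
#' @return An `imf_set`: IMFs (columns, ordered high to low frequency),
#'   residual, and `fs`. A monotone input yields zero IMFs with the input as
#'   residual.
#' @export
emd <- function(x, fs, max_imfs = 12, max_sift = 10, sd_tol = 0.2) {
  x <- as.numeric(x)
  if (length(x) < 8) stop("series too short for sifting (need >= 8 samples)")
  if (!all(is.finite(x))) stop("series must be finite")
  res <- cpp_emd(x, max_imfs = max_imfs, max_sift = max_sift, sd_tol = sd_tol)
  structure(list(imfs = res$imfs, residual = res$residual, fs = fs),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs, %d samples @ %g Hz\n",
              ncol(x$imfs), length(x$residual), x$fs))
  invisible(x)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  p + c(0, cumsum(round(-d / (2 * pi)))) * 2 * pi
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Instantaneous amplitude and frequency of each IMF: phase unwrapping and
# centered differences; one-sided at the ends.
imf_instantaneous <- function(imfset) {
  imfs <- imfset$imfs
  n <- nrow(imfs)
  k <- ncol(imfs)
  amp <- matrix(0, n, k)
  freq <- matrix(0, n, k)
  for (j in seq_len(k)) {
    z <- analytic_signal(imfs[, j])
    amp[, j] <- Mod(z)
    ph <- unwrap_phase(Arg(z))
    f <- numeric(n)
    if (n > 2) f[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) / 2
    f[1] <- ph[2] - ph[1]
    f[n] <- ph[n] - ph[n - 1]
    freq[, j] <- f * imfset$fs / (2 * pi)
  }
  list(amp = amp, freq = freq)
}

#' Hilbert spectrum of an IMF set
#'
#' Per-IMF instantaneous amplitude and frequency from the analytic signal;
#' squared amplitude is binned onto a frequency grid of resolution
#' `freq_resolution` per time sample. Negative instantaneous frequencies are
#' clipped to the lowest bin.
#'
#' @param imfset An [emd()] result.
#' @param freq_resolution Frequency grid step in Hz (default 0.1).
#' @return A `hilbert_spectrum`: `energy` (time x frequency matrix of squared
#'   amplitude), `freq_axis` (bin centers, spanning (0, fs/2]), `time_axis`.
#' @export
hilbert_spectrum <- function(imfset, freq_resolution = 0.1) {
  stopifnot(inherits(imfset, "imf_set"))
  if (freq_resolution <= 0) stop("`freq_resolution` must be positive")
  fs <- imfset$fs
  n <- length(imfset$residual)
  nbins <- ceiling((fs / 2) / freq_resolution)
  S <- matrix(0, n, nbins)
  if (ncol(imfset$imfs) > 0) {
    inst <- imf_instantaneous(imfset)
    bin <- pmin(pmax(ceiling(inst$freq / freq_resolution), 1L), nbins)
    e <- inst$amp^2
    for (j in seq_len(ncol(bin))) {
      idx <- cbind(seq_len(n), bin[, j])
      S[idx] <- S[idx] + e[, j]
    }
  }
  structure(list(energy = S,
                 freq_axis = (seq_len(nbins) - 0.5) * freq_resolution,
                 time_axis = (seq_len(n) - 1) / fs,
                 freq_resolution = freq_resolution, fs = fs),
            class = "hilbert_spectrum")
}

# Band energy of one epoch channel without materialising the full
# time-frequency matrix; numerically identical to averaging the
# hilbert_spectrum() grid over each band's bins.
band_energy_fast <- function(x, fs, bands, freq_resolution = 0.1,
                             max_imfs = 12, max_sift = 10, sd_tol = 0.2) {
  imfset <- emd(x, fs, max_imfs = max_imfs, max_sift = max_sift, sd_tol = sd_tol)
  nbins <- ceiling((fs / 2) / freq_resolution)
  nb <- nrow(bands)
  centres_all <- (seq_len(nbins) - 0.5) * freq_resolution
  bins_per_band <- vapply(seq_len(nb), function(b) {
    max(1L, sum(centres_all > bands$lo[b] & centres_all <= bands$hi[b]))
  }, integer(1))
  out <- numeric(nb)
  if (ncol(imfset$imfs) == 0)
    return(out)
  inst <- imf_instantaneous(imfset)
  bin <- pmin(pmax(ceiling(inst$freq / freq_resolution), 1L), nbins)
  centre <- (bin - 0.5) * freq_resolution
  e <- inst$amp^2
  for (b in seq_len(nb)) {
    sel <- centre > bands$lo[b] & centre <= bands$hi[b]
    out[b] <- sum(e[sel]) / (bins_per_band[b] * length(x))
  }
  out
}

#' Per-epoch, per-channel rhythm band powers via the Hilbert-Huang transform
#'
#' For every epoch and channel, decomposes the signal by EMD, forms the
#' Hilbert spectrum at `freq_resolution`, and averages the spectral energy
#' over each rhythm's frequency bins. Flattening one epoch's slice gives the
#' per-epoch feature vector of length rhythms x channels (75 for the
#' 15-channel montage).
#'
#' @param epochs An [epoch_signal()] result.
#' @param edges Band table as from [rhythm_bands()].
#' @param freq_resolution Hilbert-spectrum resolution in Hz (default 0.1).
#' @return A `band_power_table`: `power` array (epoch x channel x rhythm),
#'   channel labels, and the band table.
#' @export
band_powers <- function(epochs, edges = rhythm_bands(), freq_resolution = 0.1) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (any(edges$lo < 0) || any(edges$hi > epochs$fs / 2))
    stop("band edges must lie inside (0, fs/2)")
  ne <- length(epochs$epochs)
  nc <- length(epochs$channel_labels)
  P <- array(0, dim = c(ne, nc, nrow(edges)),
             dimnames = list(NULL, epochs$channel_labels, edges$rhythm))
  for (i in seq_len(ne)) {
    ep <- epochs$epochs[[i]]
    for (j in seq_len(nc)) {
      P[i, j, ] <- band_energy_fast(ep[j, ], epochs$fs, edges, freq_resolution)
    }
  }
  structure(list(power = P, channel_labels = epochs$channel_labels,
                 bands = edges),
            class = "band_power_table")
}

#' @export
print.band_power_table <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<band_power_table> %d epochs x %d channels x %d rhythms\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Flatten band powers into feature vectors
#'
#' @param bpt A [band_powers()] table.
#' @param per_epoch If `TRUE` (default) one row per epoch; otherwise a single
#'   row of epoch means.
#' @return Matrix with named `channel.rhythm` columns (rhythms x channels wide).
#' @export
band_feature_matrix <- function(bpt, per_epoch = TRUE) {
  d <- dim(bpt$power)
  M <- matrix(bpt$power, nrow = d[1])
  colnames(M) <- as.vector(outer(bpt$channel_labels, bpt$bands$rhythm,
                                 function(a, b) paste(a, b, sep = ".")))
  if (!per_epoch) M <- matrix(colMeans(M), nrow = 1,
                              dimnames = list(NULL, colnames(M)))
  M
}

#' Write band powers as long-format CSV
#'
#' Columns: epoch, channel, rhythm, power.
#'
#' @param bpt A [band_powers()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_band_powers_csv <- function(bpt, path) {
  d <- dim(bpt$power)
  df <- expand.grid(epoch = seq_len(d[1]),
                    channel = bpt$channel_labels,
                    rhythm = bpt$bands$rhythm,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$power <- as.vector(bpt$power)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
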