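#' Binomial high-pass filter of order k
#'
#' Applies the alternating-sign binomial filter
#' `L_k{Z(n)} = sum_{j=1}^{k} (k-1)! / ((j-1)!(k-j)!) * (-1)^(j-1) * Z(n-j+1)`,
#' which equals the (k-1)-th backward difference of the series: `k = 1` is
#' the identity, `k = 3` has coefficients (1, -2, 1).
#'
#' @param Z Numeric series.
#' @param k Filter order, >= 1.
#' @return Filtered series of length `length(Z) - k + 1` (values for n >= k).
#' @export
binomial_highpass <- function(Z, k) {
  Z <- as.numeric(Z)
  N <- length(Z)
  if (k < 1) stop("`k` must be >= 1")
  if (k > N) stop("filter order exceeds series length")
  j <- seq_len(k)
  coef <- choose(k - 1, j - 1) * (-1)^(j - 1)
  out <- as.numeric(stats::filter(Z, coef, method = "convolution", sides = 1))
  out[k:N]
}

#' Binarize a series at zero
#'
#' Elementwise threshold: values `>= 0` map to 1, negative values to 0.
#'
#' @param L Numeric series.
#' @return Integer 0/1 series of the same length.
#' @export
binarize <- function(L) as.integer(L >= 0)

#' Zero-crossing-rate statistic of an emotion trajectory
#'
#' For each filter order `k = 1..M`: apply the binomial high-pass, binarize
#' at zero, and count symbol changes `sum_n (X_n - X_{n-1})^2`. The reported
#' statistic is the `k = 1` count (the plain zero-crossing count of the
#' zero-mean trajectory); all orders are stored. The count is invariant
#' under positive rescaling of the input.
#'
#' @param trajectory An [isomap_embed()] result, or a numeric zero-mean series.
#' @param M Number of filter orders (default 4).
#' @param check_zero_mean Verify the input is zero-mean (default TRUE).
#' @return A `zcr_result`: `counts` (per k), `zcr` (the k = 1 statistic),
#'   `n` (series length).
#' @export
zcr_ec <- function(trajectory, M = 4, check_zero_mean = TRUE) {
  Z <- if (inherits(trajectory, "emotion_trajectory")) trajectory$values else
    as.numeric(trajectory)
  N <- length(Z)
  if (N < 2) stop("series too short for a crossing count")
  if (check_zero_mean && stats::sd(Z) > 0 &&
      abs(mean(Z)) > 1e-9 * stats::sd(Z))
    stop("input is not zero-mean; center it (or set check_zero_mean = FALSE)")
  M <- min(M, N - 1L)
  counts <- vapply(seq_len(M), function(k) {
    X <- binarize(binomial_highpass(Z, k))
    sum(diff(X)^2)
  }, numeric(1))
  structure(list(counts = counts, zcr = counts[1], n = N), class = "zcr_result")
}

#' Zero-crossing rate of the raw EEG signal
#'
#' The same crossing count applied directly to each (zero-meaned) channel of
#' a recording and averaged over the emotion channel set — the raw-signal
#' counterpart of the trajectory statistic, reflecting the intensity of
#' signal fluctuation.
#'
#' @param rec An [eeg_recording()].
#' @param channels Channel subset (default [emotion_channels()]).
#' @return List: `count` (mean crossings over channels), `rate` (crossings
#'   per second), per-channel counts.
#' @export
raw_signal_zcr <- function(rec, channels = emotion_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(channels, rec$channel_labels)
  if (length(missing)) stop("unknown channels: ", paste(missing, collapse = ", "))
  per_channel <- vapply(channels, function(ch) {
    z <- rec$data[ch, ]
    z <- z - mean(z)
    zcr_ec(z, M = 1, check_zero_mean = FALSE)$zcr
  }, numeric(1))
  list(count = mean(per_channel), rate = mean(per_channel) / recording_duration(rec),
       per_channel = per_channel)
}

#' Channel sets entering the cognitive load index
#'
#' The electrode subsets whose band powers feed the engagement index:
#' eight sites for alpha, eight for beta, and the full montage for theta.
#'
#' @return Named list of channel-label vectors (`alpha`, `beta`, `theta`).
#' @export
cli_channel_sets <- function() {
  list(alpha = c("Fp1", "Fp2", "F3", "T8", "Cz", "P8", "O1", "O2"),
       beta  = c("Fp1", "F3", "F7", "F8", "Fz", "F4", "T8", "Cz"),
       theta = standard_montage())
}

#' Cognitive load index: beta / (theta + alpha)
#'
#' The engagement-based index of mental load: per epoch,
#' `CLI = mean(beta over beta set) / (mean(theta over theta set) +
#' mean(alpha over alpha set))`; the per-subject value is the mean over
#' epochs. Epochs with a non-positive denominator are excluded with a
#' message. The index is invariant under common rescaling of all band
#' powers.
#'
#' @param bpt A [band_powers()] table.
#' @param channel_sets Per-band channel lists (default [cli_channel_sets()]).
#' @return A `cli_value`: `per_epoch` series, `value` (subject mean),
#'   `excluded` epoch indices.
#' @export
cognitive_load_index <- function(bpt, channel_sets = cli_channel_sets()) {
  stopifnot(inherits(bpt, "band_power_table"))
  for (b in names(channel_sets)) {
    missing <- setdiff(channel_sets[[b]], bpt$channel_labels)
    if (length(missing))
      stop("channels missing for ", b, " set: ", paste(missing, collapse = ", "))
  }
  band_mean <- function(band) {
    rowMeans(bpt$power[, channel_sets[[band]], band, drop = FALSE])
  }
  beta <- band_mean("beta")
  denom <- band_mean("theta") + band_mean("alpha")
  cli <- beta / denom
  bad <- which(!is.finite(cli) | denom <= 0)
  if (length(bad)) {
    message("excluding ", length(bad), " epoch(s) with non-positive denominator")
    cli[bad] <- NA_real_
  }
  structure(list(per_epoch = cli, value = mean(cli, na.rm = TRUE),
                 excluded = bad, channel_sets = channel_sets),
            class = "cli_value")
}

#' Fit the modulation of emotional change rate by cognitive load
#'
#' Ordinary least squares fit of `ZCR_EC = alpha * CLI + beta` across
#' participants. A negative slope means emotional activity slows as
#' cognitive load rises.
#'
#' @param cli Per-subject CLI values, or a data.frame with columns `cli` and
#'   `zcr`.
#' @param zcr Per-subject ZCR values (ignored when `cli` is a data.frame).
#' @return A `modulation_fit`: `alpha` (slope), `beta` (intercept),
#'   `se_alpha`, `residual_sd`, `n`, and the underlying `lm` fit.
#' @export
fit_modulation <- function(cli, zcr = NULL) {
  if (is.data.frame(cli)) {
    df <- data.frame(cli = cli$cli, zcr = cli$zcr)
  } else {
    df <- data.frame(cli = as.numeric(cli), zcr = as.numeric(zcr))
  }
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3) stop("need at least 3 (CLI, ZCR) points")
  if (stats::sd(df$cli) == 0) stop("CLI values are all equal; slope undefined")
  fit <- stats::lm(zcr ~ cli, data = df)
  sm <- suppressWarnings(summary(fit))  # collinear points warn harmlessly
  cf <- sm$coefficients
  structure(list(alpha = unname(cf["cli", "Estimate"]),
                 beta = unname(cf["(Intercept)", "Estimate"]),
                 se_alpha = unname(cf["cli", "Std. Error"]),
                 residual_sd = sm$sigma,
                 n = nrow(df), fit = fit),
            class = "modulation_fit")
}

#' @export
print.modulation_fit <- function(x, ...) {
  cat(sprintf("<modulation_fit> ZCR_EC = %.4f * CLI + %.4f  (se(alpha) = %.4f, n = %d)\n",
              x$alpha, x$beta, x$se_alpha, x$n))
  invisible(x)
}
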