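#' Approximate entropy (ApEn)
#'
#' Template-matching regularity statistic with self-matches included:
#' `Phi^m = mean_i ln C_i^m`, with `C_i^m` the fraction of the `n - m + 1`
#' templates within Chebyshev distance `r` of template `i`, and
#' `ApEn = Phi^m - Phi^{m+1}`. The tolerance is expressed relative to the
#' series SD (`r = F * sd(x)`), which makes the estimate invariant under
#' affine rescaling of the input; a floor of 1e-12 guards degenerate
#' constant series.
#'
#' @param x Numeric series, length > m + 1.
#' @param m Template length (default 2).
#' @param F Tolerance as a multiple of `sd(x)` (default 0.2).
#' @param r Absolute tolerance; overrides `F` when given.
#' @return Scalar ApEn (nats), >= 0 up to floating error.
#' @export
approximate_entropy <- function(x, m = 2, F = 0.2, r = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1) stop("series too short for template length m = ", m)
  if (is.null(r)) r <- F * stats::sd(x)
  r <- max(r, 1e-12)
  cpp_apen(x, m, r)
}

#' Sample entropy (SampEn)
#'
#' Like ApEn but excluding self-matches and counting over template pairs:
#' `SampEn = -ln(A / B)` with `B` the number of pairs matching at length `m`
#' and `A` at length `m + 1` (both over the first `n - m` templates). Does
#' not depend on series length for noiseless periodic input.
#'
#' @inheritParams approximate_entropy
#' @return Scalar SampEn (nats). When no pair matches at length `m + 1` the
#'   statistic is undefined and an error of class `emodyn_undefined` is
#'   signalled rather than returning a silently large value.
#' @export
sample_entropy <- function(x, m = 2, F = 0.2, r = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1) stop("series too short for template length m = ", m)
  if (is.null(r)) r <- F * stats::sd(x)
  r <- max(r, 1e-12)
  out <- cpp_sampen(x, m, r)
  if (is.na(out))
    stop(structure(class = c("emodyn_undefined", "error", "condition"),
                   list(message = "sample entropy undefined: no template matches at length m + 1",
                        call = sys.call())))
  out
}

# Ordinal pattern codes of all length-D windows (stride 1). Ties broken by
# order of appearance (stable argsort): rank_i = #{j: x_j < x_i} + #{j < i: x_j = x_i}.
ordinal_pattern_codes <- function(x, D) {
  nw <- length(x) - D + 1
  W <- matrix(0, nw, D)
  for (d in seq_len(D)) W[, d] <- x[d:(d + nw - 1)]
  ranks <- matrix(0L, nw, D)
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (i == j) next
      if (j < i) ranks[, i] <- ranks[, i] + (W[, j] <= W[, i])
      else       ranks[, i] <- ranks[, i] + (W[, j] <  W[, i])
    }
  }
  as.vector(ranks %*% D^(seq_len(D) - 1)) + 1L
}

#' Permutation entropy (PEn)
#'
#' Shannon entropy (bits) of the ordinal-pattern distribution over all
#' overlapping length-`D` windows (stride 1). Ties are broken by order of
#' appearance, so the statistic is deterministic and invariant under
#' monotone-increasing transforms of the series.
#'
#' @param x Numeric series, length >= D + 1.
#' @param D Embedding (pattern) length, >= 2 (default 3).
#' @return Scalar PEn in bits, bounded by `log2(factorial(D))`.
#' @export
permutation_entropy <- function(x, D = 3) {
  x <- as.numeric(x)
  if (D < 2) stop("`D` must be >= 2")
  if (length(x) < D + 1) stop("series too short for pattern length D = ", D)
  codes <- ordinal_pattern_codes(x, D)
  p <- tabulate(codes, nbins = D^D)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}

#' State-space correlation entropy (SSCEn)
#'
#' The series is mean-centred and delay-embedded into length-`D` pieces
#' (stride 1); stacking the pieces as columns of `Y`, the autocorrelation
#' matrix `C = t(Y) %*% Y` holds the inner products between every pair of
#' pieces. Its strict upper-triangular entries are histogrammed into `K`
#' equal-width bins over their observed range and the Shannon entropy (bits)
#' of the bin probabilities is returned. Centring plus range-relative bins
#' make the statistic invariant under affine maps `x -> a x + b` (a > 0).
#'
#' @param x Numeric series, length >= D.
#' @param D Embedding dimension (default 3).
#' @param K Histogram bin count (default 16).
#' @return Scalar SSCEn in bits, bounded by `log2(K)`; 0 when all entries
#'   fall in one bin (constant series, or `K = 1`).
#' @export
state_space_correlation_entropy <- function(x, D = 3, K = 16) {
  x <- as.numeric(x)
  if (D < 2) stop("`D` must be >= 2")
  if (K < 1) stop("`K` must be >= 1")
  if (length(x) < D + 1) stop("series too short for embedding dimension D = ", D)
  cpp_sscen(x - mean(x), D, K)
}

entropy_estimators <- function() {
  list(apen = function(x, params)
         approximate_entropy(x, m = params$m, F = params$F),
       sampen = function(x, params)
         sample_entropy(x, m = params$m, F = params$F),
       pen = function(x, params) permutation_entropy(x, D = params$D),
       sscen = function(x, params)
         state_space_correlation_entropy(x, D = params$D, K = params$K))
}

#' Default entropy parameters
#'
#' Canonical choices from the entropy literature: template length `m = 2`,
#' tolerance `F = 0.2` SD, embedding dimension `D = 3`, `K = 16` histogram
#' bins, 5-s non-overlapping windows (about one cycle of emotional change).
#'
#' @param m,F,D,K,window,step See the individual estimators; `step` defaults
#'   to `window` (non-overlapping).
#' @return Parameter list.
#' @export
entropy_params <- function(m = 2, F = 0.2, D = 3, K = 16, window = 5,
                           step = window) {
  stopifnot(m >= 1, F > 0, D >= 2, K >= 1, window > 0, step > 0)
  list(m = m, F = F, D = D, K = K, window = window, step = step)
}

#' Sliding-window entropy feature series
#'
#' Applies one or more complexity estimators to consecutive windows of each
#' channel of a recording (or plain matrix). Windows are `params$window`
#' seconds long and advance by `params$step` (default non-overlapping);
#' a trailing partial window is discarded.
#'
#' @param rec An [eeg_recording()], or a channels-by-samples matrix.
#' @param estimators Character subset of `c("apen","sampen","pen","sscen")`.
#' @param params [entropy_params()].
#' @param fs Sampling rate; taken from `rec` when it is a recording.
#' @param channels Optional channel subset (labels).
#' @return A `feature_series`: `values` (window x channel x estimator array),
#'   `timestamps` (window start times, s), channel labels, estimator names.
#' @export
sliding_feature_series <- function(rec, estimators = c("apen", "pen", "sscen"),
                                   params = entropy_params(), fs = NULL,
                                   channels = NULL) {
  if (inherits(rec, "eeg_recording")) {
    fs <- rec$fs
    labels <- rec$channel_labels
    X <- rec$data
  } else {
    if (is.null(fs)) stop("`fs` required for matrix input")
    X <- as.matrix(rec)
    labels <- rownames(X)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(X)))
  }
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing)) stop("unknown channels: ", paste(missing, collapse = ", "))
    X <- X[channels, , drop = FALSE]
    labels <- channels
  }
  ests <- entropy_estimators()
  bad <- setdiff(estimators, names(ests))
  if (length(bad)) stop("unknown estimators: ", paste(bad, collapse = ", "))
  L <- round(params$window * fs)
  S <- round(params$step * fs)
  n <- ncol(X)
  if (n < L) stop("series shorter than one window")
  starts <- seq(1L, n - L + 1L, by = S)
  vals <- array(NA_real_,
                dim = c(length(starts), nrow(X), length(estimators)),
                dimnames = list(NULL, labels, estimators))
  for (w in seq_along(starts)) {
    seg <- X[, starts[w]:(starts[w] + L - 1L), drop = FALSE]
    for (ch in seq_len(nrow(X))) {
      for (e in seq_along(estimators)) {
        vals[w, ch, e] <- ests[[estimators[e]]](seg[ch, ], params)
      }
    }
  }
  structure(list(values = vals, timestamps = (starts - 1) / fs,
                 channel_labels = labels, estimators = estimators,
                 params = params),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_series> %d windows x %d channels x %d features (%s)\n",
              d[1], d[2], d[3], paste(x$estimators, collapse = ", ")))
  invisible(x)
}

#' Flatten a feature series into a windows-by-features matrix
#'
#' Column names are `channel.estimator`.
#'
#' @param fser A [sliding_feature_series()] result.
#' @return Numeric matrix, one row per window.
#' @export
feature_series_matrix <- function(fser) {
  d <- dim(fser$values)
  M <- matrix(fser$values, nrow = d[1])
  colnames(M) <- as.vector(outer(fser$channel_labels, fser$estimators,
                                 function(a, b) paste(a, b, sep = ".")))
  M
}

#' Write a feature series as long-format CSV
#'
#' Columns: window, time, channel, feature, value.
#'
#' @param fser A [sliding_feature_series()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_series_csv <- function(fser, path) {
  d <- dim(fser$values)
  df <- expand.grid(window = seq_len(d[1]),
                    channel = fser$channel_labels,
                    feature = fser$estimators,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$time <- fser$timestamps[df$window]
  df$value <- as.vector(fser$values)
  utils::write.csv(df[, c("window", "time", "channel", "feature", "value")],
                   path, row.names = FALSE)
  invisible(path)
}
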