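# Daubechies-10 (20-tap) analysis scaling filter, the standard published
# orthonormal coefficients (sum = sqrt(2), unit energy).
db10_dec_lo <- function() {
  c(-1.3264202894521244e-05, 9.3588670320069592e-05, -1.1646685512928545e-04,
    -6.8585669495971162e-04, 1.9924052951850561e-03, 1.3953517470529011e-03,
    -1.0733175483330575e-02, 3.6065535669561697e-03, 3.3212674059341002e-02,
    -2.9457536821875813e-02, -7.1394147166397082e-02, 9.3057364603572348e-02,
    1.2736934033579325e-01, -1.9594627437737705e-01, -2.4984642432731538e-01,
    2.8117234366057747e-01, 6.8845903945360354e-01, 5.2720118893172563e-01,
    1.8817680007769150e-01, 2.6670057900555554e-02)
}

# Quadrature-mirror high-pass from the low-pass.
db10_dec_hi <- function() {
  lo <- db10_dec_lo()
  L <- length(lo)
  rev(lo) * (-1)^(seq_len(L) - 1)
}

# One periodised analysis step: a_k = sum_j f[j] v[(2k + j) mod L].
wp_step <- function(v, f) {
  L <- length(v)
  nf <- length(f)
  half <- L %/% 2L
  out <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2 * (k - 1) + seq_len(nf) - 1) %% L) + 1
    out[k] <- sum(f * v[idx])
  }
  out
}

#' Full wavelet-packet decomposition into uniform leaf bands
#'
#' Periodised 5-level wavelet-packet transform with the Daubechies-10 filter
#' pair, producing 32 leaf bands of width fs/64 tiling (0, fs/2]. Leaves are
#' returned in frequency (sequency) order, so contiguous leaf indices cover
#' contiguous frequency ranges. The input is zero-padded to the next multiple
#' of 32 samples; orthonormality makes the transform energy-preserving
#' (Parseval) on the padded series.
#'
#' @param x Numeric series (length >= the 20-tap filter support).
#' @param fs Sampling rate in Hz.
#' @param levels Tree depth (default 5, i.e. 2^5 = 32 leaves).
#' @return List: `coeffs` (list of 32 leaf coefficient vectors, frequency
#'   order), `leaf_energies`, `leaf_edges` (data.frame lo/hi in Hz), `fs`.
#' @export
wavelet_packet <- function(x, fs, levels = 5) {
  x <- as.numeric(x)
  if (length(x) < 20) stop("series shorter than the wavelet filter support")
  nl <- 2L^levels
  if (length(x) %% nl != 0) x <- c(x, numeric(nl - length(x) %% nl))
  lo <- db10_dec_lo()
  hi <- db10_dec_hi()
  nodes <- list(x)
  fpos <- 0L  # frequency position of each node at the current level
  for (lev in seq_len(levels)) {
    nxt <- vector("list", 2L * length(nodes))
    fnxt <- integer(2L * length(nodes))
    for (i in seq_along(nodes)) {
      a <- wp_step(nodes[[i]], lo)
      d <- wp_step(nodes[[i]], hi)
      p <- fpos[i]
      # sequency ordering: the high-pass branch is frequency-reversed at
      # alternate positions (Gray-code ordering of the packet tree)
      if (p %% 2L == 0L) {
        nxt[[2 * i - 1]] <- a; fnxt[2 * i - 1] <- 2L * p
        nxt[[2 * i]] <- d;     fnxt[2 * i] <- 2L * p + 1L
      } else {
        nxt[[2 * i - 1]] <- d; fnxt[2 * i - 1] <- 2L * p
        nxt[[2 * i]] <- a;     fnxt[2 * i] <- 2L * p + 1L
      }
    }
    nodes <- nxt
    fpos <- fnxt
  }
  ord <- order(fpos)
  coeffs <- nodes[ord]
  bw <- (fs / 2) / nl
  leaf_edges <- data.frame(leaf = seq_len(nl),
                           lo = (seq_len(nl) - 1) * bw,
                           hi = seq_len(nl) * bw)
  list(coeffs = coeffs,
       leaf_energies = vapply(coeffs, function(v) sum(v^2), numeric(1)),
       leaf_edges = leaf_edges, fs = fs)
}

#' Leaf-to-rhythm component mapping
#'
#' Maps contiguous wavelet-packet leaf indices to the five EEG rhythms. At
#' 125 Hz sampling the leaf bandwidth is 1.953125 Hz, so delta = leaves 1-2
#' (0-3.90625 Hz), theta = 3-4, alpha = 5-7, beta = 8-15, gamma = 16-24,
#' matching the rhythm edges of [rhythm_bands()] at the printed precision.
#'
#' @param fs Sampling rate in Hz (default 125).
#' @param levels Packet tree depth (default 5).
#' @return data.frame: rhythm, first/last leaf index, frequency range.
#' @export
rhythm_component_table <- function(fs = 125, levels = 5) {
  bw <- (fs / 2) / 2^levels
  comp <- data.frame(rhythm = c("delta", "theta", "alpha", "beta", "gamma"),
                     leaf_lo = c(1L, 3L, 5L, 8L, 16L),
                     leaf_hi = c(2L, 4L, 7L, 15L, 24L))
  comp$f_lo <- (comp$leaf_lo - 1) * bw
  comp$f_hi <- comp$leaf_hi * bw
  comp
}

#' Rhythm energies from the wavelet-packet decomposition
#'
#' Sums leaf energies into the five rhythms per the component mapping.
#' `E_total` is the energy over all 32 leaves (= energy of the padded
#' series, by Parseval).
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param components Mapping as from [rhythm_component_table()].
#' @return A `rhythm_energy`: `E` (named rhythm energies), `E_total`,
#'   `component_map`, `leaf_energies`, `leaf_edges`.
#' @export
wavelet_rhythm_energies <- function(x, fs, components = rhythm_component_table(fs)) {
  wp <- wavelet_packet(x, fs)
  E <- vapply(seq_len(nrow(components)), function(i) {
    sum(wp$leaf_energies[components$leaf_lo[i]:components$leaf_hi[i]])
  }, numeric(1))
  names(E) <- components$rhythm
  structure(list(E = E, E_total = sum(wp$leaf_energies),
                 component_map = components,
                 leaf_energies = wp$leaf_energies, leaf_edges = wp$leaf_edges),
            class = "rhythm_energy")
}

#' Wavelet energy ratios and wavelet entropy
#'
#' Energy ratio `R_i = E_i / E_total` per rhythm, and the wavelet entropy
#' `We = -sum_i R_i ln R_i` (natural log, with 0 ln 0 = 0). Because the five
#' rhythms cover only 0-46.9 Hz of the analysed band, `sum(R) <= 1`.
#'
#' @param energies A [wavelet_rhythm_energies()] result.
#' @return List: `R` (named ratios), `We` (nats).
#' @export
wavelet_entropy <- function(energies) {
  stopifnot(inherits(energies, "rhythm_energy"))
  if (energies$E_total <= 0) stop("zero total energy: wavelet entropy undefined")
  R <- energies$E / energies$E_total
  nz <- R > 0
  We <- -sum(R[nz] * log(R[nz]))
  list(R = R, We = We)
}

#' Wavelet rhythm features for an epoch set
#'
#' Energy ratios and wavelet entropy per epoch and channel, in long format.
#'
#' @param epochs An [epoch_signal()] result.
#' @return data.frame: epoch, channel, rhythm, R (energy ratio), We
#'   (wavelet entropy of that epoch/channel).
#' @export
wavelet_feature_table <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  comp <- rhythm_component_table(epochs$fs)
  rows <- list()
  for (i in seq_along(epochs$epochs)) {
    ep <- epochs$epochs[[i]]
    for (ch in seq_len(nrow(ep))) {
      en <- wavelet_rhythm_energies(ep[ch, ], epochs$fs, comp)
      we <- wavelet_entropy(en)
      rows[[length(rows) + 1]] <-
        data.frame(epoch = i, channel = epochs$channel_labels[ch],
                   rhythm = names(we$R), R = unname(we$R), We = we$We)
    }
  }
  do.call(rbind, rows)
}
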