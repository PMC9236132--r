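# Independent brute-force oracles, kept deliberately naive (explicit loops,
# direct counting) so they share no code path with the package kernels.

apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logs <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

pen_oracle <- function(x, D) {
  nw <- length(x) - D + 1
  pats <- character(nw)
  for (w in seq_len(nw)) {
    seg <- x[w:(w + D - 1)]
    pats[w] <- paste(order(seg), collapse = ",")  # stable: order() ties by index
  }
  p <- table(pats) / nw
  -sum(p * log2(p))
}

sscen_oracle <- function(x, D, K) {
  x <- x - mean(x)
  nw <- length(x) - D + 1
  v <- c()
  for (i in seq_len(nw - 1)) {
    for (j in (i + 1):nw) {
      v <- c(v, sum(x[i:(i + D - 1)] * x[j:(j + D - 1)]))
    }
  }
  if (K <= 1 || max(v) == min(v)) return(0)
  wdt <- (max(v) - min(v)) / K
  b <- pmin(floor((v - min(v)) / wdt), K - 1)
  p <- table(b) / length(v)
  -sum(p * log2(p))
}

# Periodogram band power: mean squared-FFT power over Fourier frequencies
# inside (lo, hi]. Used as the spectral oracle for generator checks.
periodogram_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  half <- f > 0 & f <= fs / 2
  sum(P[half & f > lo & f <= hi]) / sum(P[half])
}
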