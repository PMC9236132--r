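# Run code with an isolated RNG state (restores the caller's .Random.seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort configuration for the synthetic-EEG generator
#'
#' Defaults encode the emulated study conditions: two groups ("grayscale",
#' the higher-load condition, and "color", the lower-load condition) of 19
#' participants each, 5-minute recordings at 125 Hz over the 15-channel
#' 10/20 montage. Per-condition relative band powers are chosen so the
#' grayscale condition has the larger beta/(theta+alpha) engagement index
#' and the broader, noisier spectrum (hence higher complexity), and its
#' latent emotion state fluctuates more slowly (3 vs 8 sign changes per
#' minute) — together implying a negative trajectory-ZCR-vs-CLI slope.
#'
#' @param n_per_condition Participants per condition (default 19).
#' @param duration Recording length in seconds (default 300).
#' @param fs Sampling rate in Hz (default 125).
#' @param channels Montage labels (default [standard_montage()]).
#' @param band_gains Per-condition named list: relative power per rhythm.
#' @param noise_scale Per-condition 1/f background-noise SD (arbitrary
#'   units; signals are z-scored per channel on output).
#' @param noise_exponent Spectral slope of the 1/f background (default 1).
#' @param broadband_scale Per-condition SD of the white broadband noise
#'   floor.
#' @param emotion_rate Per-condition latent-state fluctuation rate, mean
#'   sign changes per minute.
#' @param emotion_channels Channels whose alpha rhythm is modulated by the
#'   latent state (default [emotion_channels()]).
#' @param modulation_depth Log-amplitude modulation depth of the alpha
#'   rhythm by the (unit-variance) latent state (default 1.0).
#' @param subject_jitter_sd SD of per-participant lognormal jitter applied
#'   to band gains and noise scale (default 0.1).
#' @param seed Base seed; participant seeds are derived as seed + index.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_condition = 19,
                          duration = 300,
                          fs = 125,
                          channels = standard_montage(),
                          band_gains = list(
                            grayscale = c(delta = 1.0, theta = 0.6, alpha = 0.7,
                                          beta = 1.3, gamma = 0.9),
                            color = c(delta = 1.0, theta = 1.1, alpha = 1.3,
                                      beta = 0.5, gamma = 0.35)),
                          noise_scale = c(grayscale = 1.0, color = 0.55),
                          noise_exponent = 1,
                          broadband_scale = c(grayscale = 0.6, color = 0.35),
                          emotion_rate = c(grayscale = 3, color = 8),
                          emotion_channels = emodyn::emotion_channels(),
                          modulation_depth = 1.0,
                          subject_jitter_sd = 0.1,
                          seed = 1L) {
  cfg <- list(n_per_condition = n_per_condition, duration = duration, fs = fs,
              channels = channels, band_gains = band_gains,
              noise_scale = noise_scale, noise_exponent = noise_exponent,
              broadband_scale = broadband_scale,
              emotion_rate = emotion_rate, emotion_channels = emotion_channels,
              modulation_depth = modulation_depth,
              subject_jitter_sd = subject_jitter_sd, seed = as.integer(seed))
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_per_condition < 2) stop("`n_per_condition` must be >= 2")
  if (cfg$duration <= 0) stop("`duration` must be positive")
  if (cfg$fs <= 0) stop("`fs` must be positive")
  conds <- names(cfg$band_gains)
  if (length(conds) != 2) stop("exactly two conditions are supported")
  for (cond in conds) {
    g <- cfg$band_gains[[cond]]
    if (!all(rhythm_bands()$rhythm %in% names(g)))
      stop("band_gains for ", cond, " must name all five rhythms")
    if (any(g <= 0)) stop("band gains must be positive")
  }
  if (!all(conds %in% names(cfg$emotion_rate)) || any(cfg$emotion_rate <= 0))
    stop("emotion_rate must be positive for each condition")
  if (!all(cfg$emotion_channels %in% cfg$channels))
    stop("emotion channels must be part of the montage")
  invisible(cfg)
}

#' Read a cohort configuration from YAML or JSON
#'
#' @param path File mirroring the [cohort_config()] fields; absent fields
#'   keep their defaults.
#' @return A `cohort_config` list.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  if (!is.null(raw$band_gains))
    raw$band_gains <- lapply(raw$band_gains, unlist)
  for (f in c("noise_scale", "emotion_rate"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(cohort_config, raw)
}

# Unit-SD band-limited noise: white noise FIR band-passed at the band edges
# (applied by FFT convolution; transients trimmed).
band_limited_noise <- function(n, fs, lo, hi, order = 256) {
  nyq <- fs / 2
  x <- stats::rnorm(n + 2 * order)
  b <- if (lo <= 0) signal::fir1(order, hi / nyq, type = "low")
       else signal::fir1(order, c(lo, min(hi, nyq * 0.999)) / nyq, type = "pass")
  y <- stats::convolve(x, rev(as.numeric(b)), type = "open")
  y <- y[(order + 1):(order + n)]
  y / stats::sd(y)
}

# Unit-SD 1/f^(exponent) power-spectrum noise via FFT amplitude shaping.
pink_noise <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  W <- W * f^(-exponent / 2)
  y <- Re(stats::fft(W, inverse = TRUE) / n)
  y / stats::sd(y)
}

# Latent emotion state: a smooth stationary Gaussian process with
# squared-exponential covariance rho(tau) = exp(-tau^2 / (2 l^2)), built by
# Gaussian-kernel smoothing of white noise on a 0.1-s grid and spline
# resampling to fs. By the Rice formula its expected zero-crossing rate is
# 1/(pi * l) per second, so l = 60 / (pi * rate_per_min) yields the
# requested sign-change rate; being differentiable, its crossings happen at
# the requested timescale rather than as fast jitter that window averaging
# would erase.
latent_emotion_state <- function(duration, fs, rate_per_min, dt = 0.1) {
  l <- 60 / (pi * rate_per_min)            # correlation length, seconds
  sigma_k <- l / sqrt(2) / dt              # kernel SD in grid steps
  halfw <- ceiling(4 * sigma_k)
  ng <- ceiling(duration / dt) + 1
  e <- stats::rnorm(ng + 2 * halfw)
  kern <- stats::dnorm(seq(-halfw, halfw), sd = sigma_k)
  s <- stats::convolve(e, rev(kern), type = "open")
  s <- s[(2 * halfw + 1):(2 * halfw + ng)]  # interior: full kernel support
  s <- (s - mean(s)) / stats::sd(s)
  tg <- (seq_len(ng) - 1) * dt
  tt <- (seq_len(round(duration * fs)) - 1) / fs
  stats::spline(tg, s, xout = tt)$y
}

#' Generate one synthetic EEG recording
#'
#' Each channel is a sum of band-limited oscillations (filtered white noise
#' per rhythm, scaled so each rhythm's relative power equals its configured
#' gain), a 1/f background, and a white broadband floor. On the emotion
#' channels the alpha rhythm's amplitude is modulated by a smooth latent
#' emotion state with the configured sign-change rate (`exp(depth * state)`
#' gain), mimicking alpha waxing and waning with emotional state: the
#' rhythm-to-broadband mix, and with it the windowed signal complexity,
#' tracks the state — whereas a whole-channel amplitude modulation would be
#' invisible to the scale-invariant complexity estimators downstream. Channels are z-scored on output; the latent state (at fs) is
#' kept in `meta$emotion_state`. Deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param condition Condition label (a name of `config$band_gains`).
#' @param seed Integer seed.
#' @return An [eeg_recording()] with condition, seed and latent state in `meta`.
#' @export
generate_recording <- function(config, condition, seed) {
  validate_cohort_config(config)
  if (!condition %in% names(config$band_gains))
    stop("unknown condition label: ", condition)
  fs <- config$fs
  n <- round(config$duration * fs)
  bands <- rhythm_bands()
  gains <- config$band_gains[[condition]][bands$rhythm]
  nz <- config$noise_scale[[condition]]
  bb <- config$broadband_scale[[condition]]
  with_seed(seed, {
    state <- latent_emotion_state(config$duration, fs,
                                  config$emotion_rate[[condition]])
    X <- matrix(0, length(config$channels), n)
    alpha_gain <- exp(config$modulation_depth * state)
    for (ch in seq_along(config$channels)) {
      emo <- config$channels[ch] %in% config$emotion_channels
      sig <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        osc <- sqrt(gains[b]) * band_limited_noise(n, fs, bands$lo[b], bands$hi[b])
        if (emo && bands$rhythm[b] == "alpha") osc <- osc * alpha_gain
        sig <- sig + osc
      }
      sig <- sig + nz * pink_noise(n, config$noise_exponent) + bb * stats::rnorm(n)
      X[ch, ] <- (sig - mean(sig)) / stats::sd(sig)
    }
    eeg_recording(X, fs = fs, channel_labels = config$channels,
                  meta = list(condition = condition, seed = seed,
                              emotion_state = state,
                              emotion_rate = config$emotion_rate[[condition]]))
  })
}

# Engagement index implied by a condition's configured gains.
gain_engagement <- function(g) g[["beta"]] / (g[["theta"]] + g[["alpha"]])

#' Generate a labelled synthetic cohort with ground truth
#'
#' Produces `2 * n_per_condition` recordings with per-participant seeds
#' derived as `seed + index`, plus a ground-truth record: which condition
#' has the higher engagement (CLI) by construction, which has the lower
#' latent fluctuation rate, and the implied sign of the trajectory-ZCR
#' versus CLI slope (negative when the higher-CLI condition fluctuates more
#' slowly). Per-participant lognormal jitter on band gains and noise scale
#' provides between-subject dispersion.
#'
#' @param config A [cohort_config()].
#' @return List: `recordings` (each an [eeg_recording()] with condition in
#'   `meta`), `ground_truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  conds <- names(config$band_gains)
  eng <- vapply(config$band_gains, gain_engagement, numeric(1))
  higher_cli <- conds[which.max(eng)]
  lower_rate <- conds[which.min(unlist(config$emotion_rate[conds]))]
  sign_true <- if (higher_cli == lower_rate) "negative" else "positive"
  labels <- rep(conds, each = config$n_per_condition)
  recordings <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    subj_cfg <- config
    jit <- with_seed(config$seed + 500000L + i, {
      stats::rlnorm(7, 0, config$subject_jitter_sd)
    })
    subj_cfg$band_gains[[labels[i]]] <-
      subj_cfg$band_gains[[labels[i]]] * jit[1:5]
    subj_cfg$noise_scale[[labels[i]]] <-
      subj_cfg$noise_scale[[labels[i]]] * jit[6]
    subj_cfg$broadband_scale[[labels[i]]] <-
      subj_cfg$broadband_scale[[labels[i]]] * jit[7]
    rec <- generate_recording(subj_cfg, labels[i], seed = config$seed + i)
    rec$meta$subject <- sprintf("S%02d", i)
    recordings[[i]] <- rec
  }
  list(recordings = recordings,
       ground_truth = list(condition = labels,
                           subject = vapply(recordings,
                                            function(r) r$meta$subject,
                                            character(1)),
                           higher_cli_condition = higher_cli,
                           lower_emotion_rate_condition = lower_rate,
                           true_modulation_sign = sign_true))
}
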