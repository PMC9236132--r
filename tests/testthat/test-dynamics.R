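test_that("the binomial filter reduces to known closed forms", {
  set.seed(1)
  Z <- rnorm(20)
  expect_equal(binomial_highpass(Z, 1), Z)
  # impulse response at k = 3: coefficients (1, -2, 1)
  imp <- c(0, 0, 1, rep(0, 7))
  expect_equal(binomial_highpass(imp, 3), c(1, -2, 1, rep(0, 5)))
  expect_equal(binomial_highpass(rep(4, 10), 2), rep(0, 9))
  expect_error(binomial_highpass(Z, 25), "exceeds")
})

test_that("order k equals the (k-1)-th backward difference", {
  set.seed(2)
  Z <- rnorm(60)
  for (k in 2:6) {
    expect_equal(binomial_highpass(Z, k), diff(Z, differences = k - 1),
                 tolerance = 1e-12)
  }
})

test_that("binarize thresholds at zero with >= mapping to 1", {
  expect_equal(binarize(c(0.5, -0.2, 0)), c(1L, 0L, 1L))
  expect_equal(binarize(c(-3, -1e-9)), c(0L, 0L))
  b <- binarize(rnorm(50))
  expect_true(all(b %in% c(0L, 1L)))
})

test_that("ZCR_EC counts symbol changes as in the worked example", {
  res <- zcr_ec(c(1, -1, 1, -1, 1), M = 1, check_zero_mean = FALSE)
  expect_equal(res$zcr, 4)
  expect_equal(zcr_ec(c(2, 5, 1, 9), check_zero_mean = FALSE)$zcr, 0)
  expect_error(zcr_ec(3), "too short")
  expect_error(zcr_ec(c(1, 2, 3)), "not zero-mean")
})

test_that("ZCR_EC is invariant under positive rescaling", {
  set.seed(3)
  Z <- rnorm(200)
  Z <- Z - mean(Z)
  r1 <- zcr_ec(Z, M = 4)
  r2 <- zcr_ec(17.3 * Z, M = 4)
  expect_equal(r1$counts, r2$counts)
})

test_that("higher-order counts stay within the count bounds", {
  set.seed(4)
  Z <- rnorm(300)
  Z <- Z - mean(Z)
  res <- zcr_ec(Z, M = 4)
  expect_true(all(res$counts >= 0 & res$counts <= res$n - 1))
  expect_equal(res$counts, round(res$counts))
})

make_bpt <- function(power) {
  # power: epoch x channel x rhythm with the standard montage
  structure(list(power = power, channel_labels = standard_montage(),
                 bands = rhythm_bands()),
            class = "band_power_table")
}

test_that("the cognitive load index matches hand-computed ratios", {
  P <- array(1, dim = c(2, 15, 5),
             dimnames = list(NULL, standard_montage(), rhythm_bands()$rhythm))
  expect_equal(cognitive_load_index(make_bpt(P))$value, 0.5)
  P[, , "beta"] <- 2
  expect_equal(cognitive_load_index(make_bpt(P))$value, 1.0)
  # scale invariance
  expect_equal(cognitive_load_index(make_bpt(P * 7))$value, 1.0)
})

test_that("epochs with a non-positive denominator are excluded with a message", {
  P <- array(1, dim = c(3, 15, 5),
             dimnames = list(NULL, standard_montage(), rhythm_bands()$rhythm))
  P[2, , c("theta", "alpha")] <- 0
  expect_message(cli <- cognitive_load_index(make_bpt(P)), "excluding 1 epoch")
  expect_equal(cli$excluded, 2L)
  expect_equal(cli$value, 0.5)
})

test_that("the modulation fit recovers exact lines and shifts correctly", {
  fit <- fit_modulation(c(1, 2, 3), c(1, 3, 5))
  expect_equal(fit$alpha, 2, tolerance = 1e-12)
  expect_equal(fit$beta, -1, tolerance = 1e-12)
  set.seed(5)
  cli <- runif(20); zcr <- 3 * cli + rnorm(20)
  f1 <- fit_modulation(cli, zcr)
  f2 <- fit_modulation(cli, zcr + 10)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-12)
  expect_equal(f2$beta, f1$beta + 10, tolerance = 1e-12)
  expect_error(fit_modulation(c(1, 1, 1), c(1, 2, 3)), "all equal")
  expect_error(fit_modulation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("raw-signal ZCR averages crossing counts over the emotion channels", {
  fs <- 125
  t <- (0:(4 * fs - 1)) / fs
  data <- matrix(rep(sin(2 * pi * 5 * t), 15), nrow = 15, byrow = TRUE)
  rec <- eeg_recording(data, fs, standard_montage())
  z <- raw_signal_zcr(rec)
  expect_equal(z$count, 2 * 5 * 4 - 1)  # 5 Hz for 4 s: 39 sign changes
  expect_equal(z$rate, z$count / 4)
  expect_error(raw_signal_zcr(rec, channels = "Oz"), "unknown channels")
})
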