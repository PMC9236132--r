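test_that("generation is bit-identical for a fixed seed", {
  cfg <- cohort_config(duration = 10, n_per_condition = 2)
  r1 <- generate_recording(cfg, "grayscale", 42)
  r2 <- generate_recording(cfg, "grayscale", 42)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$meta$emotion_state, r2$meta$emotion_state)
  r3 <- generate_recording(cfg, "grayscale", 43)
  expect_false(identical(r1$data, r3$data))
})

test_that("recording shape follows duration, fs and montage", {
  cfg <- cohort_config(duration = 300, n_per_condition = 2)
  rec <- generate_recording(cfg, "color", 1)
  expect_equal(dim(rec$data), c(15, 37500))
  expect_identical(rec$channel_labels, standard_montage())
})

test_that("unknown condition and invalid configs are rejected", {
  cfg <- cohort_config(duration = 5, n_per_condition = 2)
  expect_error(generate_recording(cfg, "sepia", 1), "unknown condition")
  expect_error(cohort_config(n_per_condition = 1), "n_per_condition")
  expect_error(cohort_config(duration = 0), "duration")
  expect_error(cohort_config(emotion_rate = c(grayscale = -1, color = 8)),
               "emotion_rate")
})

test_that("an alpha-only, noise-free config concentrates power in the alpha band", {
  gains <- c(delta = 1e-8, theta = 1e-8, alpha = 1, beta = 1e-8, gamma = 1e-8)
  cfg <- cohort_config(duration = 40, n_per_condition = 2,
                       band_gains = list(grayscale = gains, color = gains),
                       noise_scale = c(grayscale = 0, color = 0),
                       broadband_scale = c(grayscale = 0, color = 0),
                       modulation_depth = 0)
  rec <- generate_recording(cfg, "grayscale", 5)
  for (ch in seq_len(nrow(rec$data))) {
    frac <- periodogram_band_fraction(rec$data[ch, ], cfg$fs, 7.8, 13.7)
    expect_gt(frac, 0.90)
  }
})

test_that("empirical band-power ratios match configured gains within 15%", {
  gains <- c(delta = 1.0, theta = 0.6, alpha = 0.7, beta = 1.3, gamma = 0.9)
  cfg <- cohort_config(duration = 120, n_per_condition = 2,
                       band_gains = list(grayscale = gains, color = gains),
                       noise_scale = c(grayscale = 0, color = 0),
                       broadband_scale = c(grayscale = 0, color = 0),
                       modulation_depth = 0)
  rec <- generate_recording(cfg, "grayscale", 9)
  bd <- rhythm_bands()
  fr <- vapply(seq_len(nrow(bd)), function(b)
    periodogram_band_fraction(rec$data[3, ], cfg$fs, bd$lo[b], bd$hi[b]),
    numeric(1))
  expect_equal(fr / sum(fr), unname(gains / sum(gains)), tolerance = 0.15)
})

test_that("latent state sign-change rate matches the configured rate", {
  for (rate in c(3, 8)) {
    rates <- vapply(1:5, function(s) {
      st <- emodyn:::with_seed(s,
        emodyn:::latent_emotion_state(600, 125, rate))
      sum(diff(sign(st)) != 0) / 10   # crossings per minute over 10 min
    }, numeric(1))
    expect_equal(mean(rates), rate, tolerance = 0.2)
  }
})

test_that("cohorts carry labels, derived seeds and consistent ground truth", {
  cfg <- cohort_config(duration = 5, n_per_condition = 2)
  ch <- generate_cohort(cfg)
  expect_length(ch$recordings, 4)
  expect_equal(sum(ch$ground_truth$condition == "grayscale"), 2)
  expect_equal(sum(ch$ground_truth$condition == "color"), 2)
  # grayscale has the larger beta/(theta+alpha) gains and the lower rate
  expect_equal(ch$ground_truth$higher_cli_condition, "grayscale")
  expect_equal(ch$ground_truth$lower_emotion_rate_condition, "grayscale")
  expect_equal(ch$ground_truth$true_modulation_sign, "negative")
  seeds <- vapply(ch$recordings, function(r) r$meta$seed, numeric(1))
  expect_equal(seeds, cfg$seed + 1:4)
})

test_that("full-size cohort has 19 recordings per condition", {
  cfg <- cohort_config(duration = 1, n_per_condition = 19)
  ch <- generate_cohort(cfg)
  expect_length(ch$recordings, 38)
  expect_equal(unname(table(ch$ground_truth$condition)), c(19L, 19L),
               ignore_attr = TRUE)
})

test_that("CSV + sidecar roundtrip preserves the recording", {
  cfg <- cohort_config(duration = 4, n_per_condition = 2)
  rec <- generate_recording(cfg, "color", 3)
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording_csv(rec, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_recording_csv(path, montage = standard_montage())
  expect_equal(back$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$meta$condition, "color")
})

test_that("cohort configs read back from YAML and JSON", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("n_per_condition: 3", "duration: 12", "seed: 7"), yml)
  cfg <- read_cohort_config(yml)
  expect_equal(cfg$n_per_condition, 3)
  expect_equal(cfg$duration, 12)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$fs, 125)
  jsn <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(n_per_condition = 4, duration = 6), jsn,
                       auto_unbox = TRUE)
  expect_equal(read_cohort_config(jsn)$n_per_condition, 4)
  writeLines("not_a_field: 1", yml)
  expect_error(read_cohort_config(yml), "unknown config fields")
})
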