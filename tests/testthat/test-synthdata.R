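test_that("feature tables are reproducible and match configured means", {
  cfg <- default_synth_config()
  a <- suppressMessages(simulate_feature_table(cfg, seed = 11))
  b <- suppressMessages(simulate_feature_table(cfg, seed = 11))
  expect_identical(a$features, b$features)
  expect_equal(nrow(a$features), 457L)
  expect_equal(as.vector(table(a$features$label)[c("control",
    "propranolol", "isoproterenol")]), c(145L, 100L, 212L))

  # per-condition sample means within 3 SE of the generator means
  for (cond in cfg$conditions) {
    rows <- a$features[a$features$label == cond$label, ]
    truth <- pulse_metrics(cond$pulse_mean)
    for (nm in c("h_max", "m_up", "w")) {
      se <- sd(rows[[nm]]) / sqrt(nrow(rows))
      expect_lt(abs(mean(rows[[nm]]) - truth[[nm]]), 3 * se + 0.02 *
                  abs(truth[[nm]]))
    }
  }
})

test_that("label-free structure yields chance-level forest accuracy", {
  # three identical conditions: features carry no class information
  cc <- lapply(c("a", "b", "c"), function(l)
    fixed_condition(l, n_waveforms = 100L,
                    sds = c(amplitude = 0.02, rise = 0.01)))
  cfg <- synth_config(cc, n_recordings = 5L)
  ft <- suppressMessages(simulate_feature_table(cfg, seed = 5))$features
  m <- train_forest(ft, n_trees = 50, seed = 6)
  oob_acc <- 1 - m$oob_error[50]
  expect_lt(abs(oob_acc - 1 / 3), 0.10)
})

test_that("zero variance with distinct means is perfectly separable", {
  cc <- list(
    fixed_condition("a", pulse = pulse_params(0.10, 0.08, 0.2, 0.2, 0.9),
                    n_waveforms = 60L),
    fixed_condition("b", pulse = pulse_params(0.20, 0.05, 0.2, 0.2, 0.9),
                    n_waveforms = 60L))
  cfg <- synth_config(cc, n_recordings = 2L)
  ft <- simulate_feature_table(cfg, seed = 2)$features
  sp <- stratified_split(ft, 0.5, seed = 3)
  m <- train_forest(sp$train, n_trees = 50, seed = 4)
  pred <- predict(m, sp$validation)
  expect_equal(mean(pred$predicted == pred$truth), 1)
})

test_that("simulated recordings carry the configured beat count", {
  # clean conditions: no noise, no motion, no bleach decay
  cfg <- tiny_config(n_lines = 4000L, line_period = 0.005)
  sim <- simulate_recording(cfg, "control", seed = 9)
  expect_s3_class(sim$recording, "line_scan_recording")
  n_true <- length(sim$truth$onsets)
  ctr <- detect_membranes(sim$recording)
  tr <- track_membrane(sim$recording, ctr[1])
  norm <- correct_photobleach(tr)$trace
  sm <- smooth_trace(norm, window = 11)
  b <- detect_beats(sm)
  expect_equal(b$n_beats, n_true)
  expect_equal(b$beat_rate, sim$truth$beat_rate, tolerance = 0.05)
})

test_that("zero-amplitude pulses give a null recording", {
  cfg <- tiny_config(n_lines = 600L)
  cfg$conditions$control$pulse_sd[] <- 0
  cfg$conditions$control$pulse_mean$amplitude <- 1e-9
  sim <- simulate_recording(cfg, "control", seed = 3)
  rng <- apply(sim$recording$intensity, 2, function(col)
    diff(range(col)))
  expect_lt(max(rng) / max(sim$recording$intensity), 1e-6)
})

test_that("generator guards: unresolvable membranes and out-of-frame motion", {
  cfg <- tiny_config(n_lines = 300L, n_membranes = 5L, psf_sigma = 6)
  expect_warning(simulate_recording(cfg, "control", seed = 1),
                 "unresolvable")
  cfg2 <- tiny_config(n_lines = 300L, motion_amplitude = 70)
  expect_error(simulate_recording(cfg2, "control", seed = 1),
               "out of frame")
})

test_that("recordings round-trip through TIFF + sidecar", {
  cfg <- tiny_config(n_lines = 200L, noise_sd = 20)
  sim <- simulate_recording(cfg, "isoproterenol", seed = 4)
  path <- file.path(tempdir(), "rec.tif")
  write_recording(sim$recording, path)
  back <- read_recording(path)
  expect_equal(back$intensity, round(sim$recording$intensity))
  expect_equal(back$line_period, sim$recording$line_period)
  expect_equal(back$metadata$label, "isoproterenol")
  unlink(c(path, paste0(path, ".yml")))
})

test_that("config YAML round-trips", {
  cfg <- default_synth_config()
  path <- file.path(tempdir(), "cfg.yml")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back$conditions$control$pulse_mean$amplitude,
               cfg$conditions$control$pulse_mean$amplitude)
  expect_equal(back$bleach, cfg$bleach)
  expect_equal(back$n_lines, cfg$n_lines)
  unlink(path)
})
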