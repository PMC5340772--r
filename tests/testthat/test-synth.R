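test_that("noise-free uncoupled signal is the exact sum of two sinusoids", {
  cfg <- synth_config(duration_s = 2, fs_hz = 1000, coupling_depth = 0,
                      noise_amp_uv = 0, line_amp_uv = 0, seed = 1)
  r <- gen_coupled_eeg(cfg)
  t <- (0:1999) / 1000
  expected <- 100 * cos(2 * pi * 8 * t) + 30 * cos(2 * pi * 78 * t)
  expect_equal(r$samples, expected, tolerance = 1e-12)
})

test_that("generated oscillators appear at their configured frequencies", {
  cfg <- synth_config(4.1, theta_freq_hz = 8, gamma_freq_hz = 78,
                      coupling_depth = 0.8, seed = 1)
  r <- gen_coupled_eeg(cfg)
  sp <- power_spectrum(r$samples, 2000)
  df <- 2000 / 2048
  top <- order(sp$power, decreasing = TRUE)
  # strongest bin within one FFT bin of theta; a local maximum at gamma
  expect_lt(abs(sp$freqs[top[1]] - 8), df + 1e-9)
  g_bin <- which.min(abs(sp$freqs - 78))
  g_region <- sp$power[(g_bin - 6):(g_bin + 6)]
  expect_equal(which.max(g_region), 7, tolerance = 1)
})

test_that("identical config and seed give bit-identical recordings", {
  cfg <- synth_config(1, seed = 42)
  expect_identical(gen_coupled_eeg(cfg)$samples, gen_coupled_eeg(cfg)$samples)
  e1 <- gen_experiment("mk801_w1", seed = 9, fs_hz = 500)
  e2 <- gen_experiment("mk801_w1", seed = 9, fs_hz = 500)
  expect_identical(e1$recording$samples, e2$recording$samples)
})

test_that("gamma-envelope modulation depth equals coupling_depth", {
  for (d in c(0.2, 0.5, 0.8)) {
    cfg <- synth_config(4.1, theta_amp_uv = 0, coupling_depth = d,
                        noise_amp_uv = 0, line_amp_uv = 0, seed = 1)
    r <- gen_coupled_eeg(cfg)
    env <- Mod(hilbert_fft(r$samples))
    env <- env[500:(length(env) - 500)]
    depth <- (max(env) - min(env)) / (max(env) + min(env))
    expect_equal(depth, d, tolerance = 0.01)
  }
})

test_that("invalid generator configs are rejected with the violated invariant", {
  expect_error(synth_config(4.1, coupling_depth = 1.2), "coupling_depth")
  expect_error(synth_config(-1), "duration_s")
  expect_error(synth_config(4.1, fs_hz = 100, gamma_freq_hz = 78), "fs_hz")
})

test_that("stimulation schedules follow the tetanus design", {
  ev <- gen_stim_schedule(10, 10, 0.025, 100)
  hfs <- ev[ev$kind == "hfs_train", ]
  expect_equal(hfs$time_s, seq(0, 90, by = 10))
  expect_equal(unique(hfs$duration_s), 15 / 200)  # 75 ms per train
  ev0 <- gen_stim_schedule(0, 10, 0.025, 100)
  expect_true(all(ev0$kind == "test_pulse"))
  ev1 <- gen_stim_schedule(1, 10, 0.025, 100)
  expect_equal(sum(ev1$kind == "hfs_train"), 1)
  expect_error(gen_stim_schedule(2, 0.05, 0.025, 100), "overlap")
})

test_that("artifact injection changes only the event intervals", {
  cfg <- synth_config(30, fs_hz = 500, seed = 3)
  r <- gen_coupled_eeg(cfg)
  expect_identical(inject_artifacts(r, empty_events()), r)
  ev <- stim_event(10, "hfs_train", 0.075)
  r2 <- inject_artifacts(r, ev)
  inside <- seq(floor(10 * 500) + 1, floor(10.075 * 500) + 2)
  expect_gt(max(abs(r2$samples[inside])), max(abs(r$samples)))
  expect_equal(r2$samples[-inside], r$samples[-inside])
})

test_that("ten injected trains produce at least ten disjoint artifact intervals", {
  cfg <- synth_config(120, fs_hz = 500, seed = 4)
  r <- gen_coupled_eeg(cfg)
  sched <- gen_stim_schedule(10, 10, 0.025, 120, hfs_start_s = 5)
  r2 <- inject_artifacts(r, sched)
  mask <- abs(r2$samples) > 5 * sqrt(mean(r$samples^2))
  runs <- rle(mask)
  expect_gte(sum(runs$values), 10)
})

test_that("evoked sweeps obey the plasticity decay law", {
  m <- plasticity_model(baseline_slope_mv_ms = 2.5, baseline_ps_mv = 3,
                        potentiation_factor = 1.5, decay_tau_min = 240,
                        sweep_noise_frac = 0)
  expect_equal(fepsp_slope(gen_evoked_sweep(m)), 2.5, tolerance = 1e-6)
  expect_equal(fepsp_slope(gen_evoked_sweep(m, t_min = 1e-9)), 3.75,
               tolerance = 1e-6)
  # exp(-1440/240) = 0.0025: a day later the sweep is within 1% of baseline
  f24 <- potentiation_at(m, 1440)
  expect_lt(abs(f24 - 1), 0.01)
  expect_equal(fepsp_slope(gen_evoked_sweep(m, t_min = 1440)), 2.5 * f24,
               tolerance = 1e-6)
})

test_that("experiment presets attach the scenario ground truth", {
  ctrl <- gen_experiment("control", seed = 1, fs_hz = 500)
  expect_identical(ctrl$truth$decay_tau, Inf)
  mk <- gen_experiment("mk801_w1", seed = 1, fs_hz = 500)
  expect_lt(mean(mk$truth$coupling_during[6:10]),
            mean(mk$truth$coupling_during[1:5]))
  expect_gte(recording_duration(mk$recording), 500)
  expect_error(gen_experiment("bogus", seed = 1), "arg")
})

test_that("recordings round-trip through the two-file text format", {
  cfg <- synth_config(15, fs_hz = 500, seed = 5)
  ev <- rbind(stim_event(1, "hfs_train", 0.075),
              stim_event(5, "test_pulse", 2e-4))
  r <- recording(gen_coupled_eeg(cfg)$samples, 500, ev, "control", "rat1",
                 truth = list(depth = 0.8))
  stem <- file.path(tempdir(), "rec-test")
  write_recording(r, stem)
  r2 <- read_recording(stem)
  expect_equal(r2$samples, r$samples, tolerance = 1e-10)
  expect_equal(r2$fs_hz, 500)
  expect_equal(r2$events$time_s, r$events$time_s)
  expect_equal(r2$condition, "control")
  expect_equal(r2$truth$depth, 0.8)
})
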