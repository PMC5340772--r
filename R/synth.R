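#' Configuration for the coupled-oscillation signal generator
#'
#' Describes a synthetic local field potential: a theta sinusoid, a gamma
#' sinusoid whose instantaneous amplitude is modulated by the theta phase,
#' spectrally shaped 1/f^alpha background noise, and a mains-line component.
#' The modulation kernel is `gamma_amp * (1 + coupling_depth * cos(theta_phase
#' - coupling_phase_lag))`, so the gamma-envelope modulation depth
#' `(max - min) / (max + min)` equals `coupling_depth` exactly.
#'
#' @param duration_s Signal duration in seconds (> 0).
#' @param fs_hz Sampling rate, samples/second (default 2000).
#' @param theta_freq_hz,theta_amp_uv Theta frequency (Hz) and amplitude (uV).
#' @param gamma_freq_hz,gamma_amp_uv Gamma carrier frequency (Hz) and mean
#'   amplitude (uV).
#' @param coupling_depth Modulation depth of the gamma envelope by theta
#'   phase, dimensionless in `[0, 1]`.
#' @param coupling_phase_lag Theta phase (radians) at which the gamma
#'   envelope peaks; 0 means the envelope peaks at the theta peak.
#' @param noise_exponent Slope alpha of the 1/f^alpha background (>= 0).
#' @param noise_amp_uv RMS of the background noise in uV.
#' @param line_freq_hz,line_amp_uv Mains-line frequency (default 50 Hz) and
#'   amplitude (uV).
#' @param seed Integer seed; identical seeds give bit-identical signals.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(duration_s, fs_hz = 2000,
                         theta_freq_hz = 8, theta_amp_uv = 100,
                         gamma_freq_hz = 78, gamma_amp_uv = 30,
                         coupling_depth = 0.8, coupling_phase_lag = 0,
                         noise_exponent = 1, noise_amp_uv = 20,
                         line_freq_hz = 50, line_amp_uv = 10,
                         seed = NULL) {
  cfg <- list(duration_s = duration_s, fs_hz = fs_hz,
              theta_freq_hz = theta_freq_hz, theta_amp_uv = theta_amp_uv,
              gamma_freq_hz = gamma_freq_hz, gamma_amp_uv = gamma_amp_uv,
              coupling_depth = coupling_depth,
              coupling_phase_lag = coupling_phase_lag,
              noise_exponent = noise_exponent, noise_amp_uv = noise_amp_uv,
              line_freq_hz = line_freq_hz, line_amp_uv = line_amp_uv,
              seed = seed)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("invalid synth_config: duration_s must be > 0")
  if (coupling_depth < 0 || coupling_depth > 1)
    stop("invalid synth_config: coupling_depth must lie in [0, 1]")
  if (fs_hz <= 2 * gamma_freq_hz)
    stop("invalid synth_config: fs_hz must exceed 2 * gamma_freq_hz")
  if (noise_exponent < 0)
    stop("invalid synth_config: noise_exponent must be >= 0")
  if (any(c(theta_amp_uv, gamma_amp_uv, noise_amp_uv, line_amp_uv) < 0))
    stop("invalid synth_config: amplitudes must be >= 0")
  structure(cfg, class = "synth_config")
}

#' 1/f^alpha (power-law) Gaussian noise
#'
#' White Gaussian noise spectrally shaped in the frequency domain so its
#' power spectral density falls off as `1/f^alpha`, then rescaled to the
#' requested RMS. `alpha = 0` returns white noise.
#'
#' @param n Number of samples.
#' @param fs_hz Sampling rate (Hz).
#' @param alpha Spectral exponent (>= 0).
#' @param rms_uv Target root-mean-square amplitude (uV).
#' @return Numeric vector of length `n` with zero mean.
#' @export
gen_pink_noise <- function(n, fs_hz, alpha = 1, rms_uv = 1) {
  if (rms_uv == 0 || n < 2) return(numeric(n))
  w <- stats::rnorm(n)
  if (alpha == 0) {
    x <- w
  } else {
    f <- seq(0, fs_hz - fs_hz / n, length.out = n)
    f[f > fs_hz / 2] <- fs_hz - f[f > fs_hz / 2]  # fold to physical frequency
    scale <- c(0, f[-1]^(-alpha / 2))             # kill DC
    x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  }
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * rms_uv / s
}

#' Generate a theta-gamma coupled synthetic EEG recording
#'
#' The signal is the sum of a theta sinusoid, a gamma sinusoid whose
#' instantaneous amplitude follows `gamma_amp * (1 + d * cos(theta_phase -
#' lag))`, 1/f^alpha background noise and a mains-line sinusoid. With zero
#' noise and line amplitude and `coupling_depth = 0` the output is the exact
#' sum of two fixed sinusoids.
#'
#' @param config A [synth_config()].
#' @return An [recording()] with the generating parameters attached as
#'   `$truth`.
#' @export
gen_coupled_eeg <- function(config) {
  if (!inherits(config, "synth_config"))
    config <- do.call(synth_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- round(config$duration_s * config$fs_hz)
  t <- (seq_len(n) - 1) / config$fs_hz
  theta_phase <- 2 * pi * config$theta_freq_hz * t
  theta <- config$theta_amp_uv * cos(theta_phase)
  g_env <- config$gamma_amp_uv *
    (1 + config$coupling_depth * cos(theta_phase - config$coupling_phase_lag))
  gamma <- g_env * cos(2 * pi * config$gamma_freq_hz * t)
  noise <- gen_pink_noise(n, config$fs_hz, config$noise_exponent,
                          config$noise_amp_uv)
  line <- config$line_amp_uv * sin(2 * pi * config$line_freq_hz * t)
  recording(theta + gamma + noise + line, fs_hz = config$fs_hz,
            condition = "synthetic", subject_id = "synth",
            truth = unclass(config))
}

#' Generate a stimulation schedule
#'
#' High-frequency stimulation (HFS) trains of `pulses_per_train` pulses at
#' `pulse_rate_hz` (so each train lasts `pulses_per_train / pulse_rate_hz`
#' seconds; 15 pulses at 200 Hz = 75 ms) repeated at `train_interval_s`,
#' interleaved with low-rate test pulses.
#'
#' @param n_hfs_trains Number of HFS trains (>= 0).
#' @param train_interval_s Interval between train onsets in seconds.
#' @param tp_rate_hz Test-pulse rate in Hz (default 0.025, i.e. one per 40 s).
#' @param duration_s Schedule span in seconds.
#' @param hfs_start_s Onset of the first train (default 0).
#' @param pulses_per_train,pulse_rate_hz Train composition (defaults 15
#'   pulses at 200 Hz).
#' @param tp_duration_s Test-pulse duration (default 0.2 ms biphasic pulse).
#' @return Event data frame (columns `time_s`, `kind`, `duration_s`), sorted
#'   by time. Test pulses that would fall inside an HFS train are omitted.
#' @export
gen_stim_schedule <- function(n_hfs_trains, train_interval_s = 10,
                              tp_rate_hz = 0.025, duration_s,
                              hfs_start_s = 0, pulses_per_train = 15,
                              pulse_rate_hz = 200, tp_duration_s = 2e-4) {
  stopifnot(n_hfs_trains >= 0, duration_s > 0, tp_rate_hz > 0,
            train_interval_s > 0, pulses_per_train >= 1, pulse_rate_hz > 0)
  train_dur <- pulses_per_train / pulse_rate_hz
  if (n_hfs_trains > 1 && train_interval_s <= train_dur)
    stop(sprintf("train interval (%.3f s) must exceed train duration (%.3f s): trains would overlap",
                 train_interval_s, train_dur))
  trains <- if (n_hfs_trains > 0) {
    onsets <- hfs_start_s + (seq_len(n_hfs_trains) - 1) * train_interval_s
    onsets <- onsets[onsets + train_dur <= duration_s + 1e-9]
    if (length(onsets) < n_hfs_trains)
      stop("HFS trains do not fit inside duration_s")
    data.frame(time_s = onsets, kind = "hfs_train", duration_s = train_dur,
               stringsAsFactors = FALSE)
  } else empty_events()
  tp_times <- seq(0, duration_s - tp_duration_s, by = 1 / tp_rate_hz)
  if (nrow(trains) > 0) {
    in_train <- vapply(tp_times, function(tt)
      any(tt >= trains$time_s - 1e-9 &
            tt < trains$time_s + trains$duration_s), logical(1))
    tp_times <- tp_times[!in_train]
  }
  tps <- if (length(tp_times)) {
    data.frame(time_s = tp_times, kind = "test_pulse",
               duration_s = tp_duration_s, stringsAsFactors = FALSE)
  } else empty_events()
  validate_events(rbind(trains, tps))
}

#' Superpose stimulation artifacts on a recording
#'
#' Adds biphasic rectangular transients at each event: sample values inside
#' the event interval alternate between `+amp` and `-amp` at the pulse rate
#' (square wave), emulating the large stimulus artifacts seen during HFS.
#' Samples outside event intervals are unchanged. The default amplitude is
#' 10x the pre-injection signal RMS, which makes threshold detection
#' unambiguous.
#'
#' @param recording An `eeg_recording`.
#' @param events Event data frame (defaults to the recording's own log).
#' @param artifact_amp_uv Artifact amplitude in uV (default `10 * RMS`).
#' @param pulse_rate_hz Square-wave alternation rate inside a train.
#' @return A new `eeg_recording` with artifacts added and `events` merged
#'   into its log.
#' @export
inject_artifacts <- function(recording, events = recording$events,
                             artifact_amp_uv = NULL, pulse_rate_hz = 200) {
  stopifnot(inherits(recording, "eeg_recording"))
  events <- validate_events(events)
  x <- recording$samples
  fs <- recording$fs_hz
  dur <- length(x) / fs
  if (nrow(events) == 0) return(recording)
  if (any(events$time_s + events$duration_s > dur + 1e-9))
    stop("events extend past the end of the recording")
  if (is.null(artifact_amp_uv))
    artifact_amp_uv <- 10 * sqrt(mean(x^2))
  half_period <- max(1L, round(fs / (2 * pulse_rate_hz)))
  for (i in seq_len(nrow(events))) {
    a <- floor(events$time_s[i] * fs) + 1L
    b <- min(length(x), a + max(2L, round(events$duration_s[i] * fs)) - 1L)
    k <- seq.int(a, b)
    sign_wave <- ifelse(((k - a) %/% half_period) %% 2L == 0L, 1, -1)
    x[k] <- x[k] + artifact_amp_uv * sign_wave
  }
  out <- recording
  out$samples <- x
  out$events <- validate_events(unique(rbind(recording$events, events)))
  out
}

#' Plasticity model for evoked-response generation
#'
#' Encodes the ground-truth LTP behaviour of a synthetic subject: both the
#' fEPSP slope and the population-spike amplitude are scaled by
#' `f(t) = 1 + (potentiation_factor - 1) * exp(-t / decay_tau_min)` after
#' HFS (`f = 1` before). `decay_tau_min = Inf` encodes LTP that persists
#' (> 24 h); a finite tau encodes decaying potentiation.
#'
#' @param baseline_slope_mv_ms Pre-HFS fEPSP slope in mV/ms.
#' @param baseline_ps_mv Pre-HFS population-spike amplitude in mV.
#' @param potentiation_factor Peak post-HFS multiple of baseline (>= 1).
#' @param decay_tau_min Decay time constant in minutes (> 0 or `Inf`).
#' @param sweep_noise_frac Multiplicative per-sample noise fraction.
#' @return A list of class `plasticity_model`.
#' @export
plasticity_model <- function(baseline_slope_mv_ms = 2.5, baseline_ps_mv = 3,
                             potentiation_factor = 1.5, decay_tau_min = Inf,
                             sweep_noise_frac = 0) {
  if (potentiation_factor < 1) stop("potentiation_factor must be >= 1")
  if (!(decay_tau_min > 0)) stop("decay_tau_min must be > 0 (Inf allowed)")
  if (sweep_noise_frac < 0) stop("sweep_noise_frac must be >= 0")
  structure(list(baseline_slope_mv_ms = baseline_slope_mv_ms,
                 baseline_ps_mv = baseline_ps_mv,
                 potentiation_factor = potentiation_factor,
                 decay_tau_min = decay_tau_min,
                 sweep_noise_frac = sweep_noise_frac),
            class = "plasticity_model")
}

#' Potentiation scaling factor at a given time after HFS
#' @param model A [plasticity_model()].
#' @param t_min Minutes since HFS; negative or `NA` means pre-HFS.
#' @return `f(t)` as defined in [plasticity_model()].
#' @export
potentiation_at <- function(model, t_min) {
  stopifnot(inherits(model, "plasticity_model"))
  ifelse(is.na(t_min) | t_min < 0, 1,
         1 + (model$potentiation_factor - 1) * exp(-t_min / model$decay_tau_min))
}

#' Generate one synthetic evoked field-potential sweep
#'
#' The waveform (in mV, positive-going as recorded in the dentate granule
#' cell layer) follows the stereotyped field-potential shape: flat until the
#' stimulus, a 1 ms latency, a linear fEPSP rise of slope
#' `baseline_slope * f(t)` lasting 2 ms, a 1 ms shoulder, a smooth
#' (raised-cosine) negative-going population spike whose tangent-line
#' amplitude is exactly `baseline_ps * f(t)`, a second 1 ms shoulder, and a
#' linear decay back to baseline. The shoulders flanking the spike make the
#' two positive peaks of the tangent construction well defined.
#' Multiplicative Gaussian noise of fraction `sweep_noise_frac` is applied
#' per sample.
#'
#' @param model A [plasticity_model()].
#' @param t_min Minutes since HFS (negative or `NA` = pre-HFS sweep).
#' @param seed Optional integer seed.
#' @param fs_hz Sweep sampling rate (default 20 kHz).
#' @param stim_time_s Stimulus time within the sweep (default 5 ms).
#' @param duration_s Sweep duration (default 30 ms).
#' @param intensity_ua Stimulation intensity label in microamps.
#' @return An object of class `evoked_sweep` with fields `samples` (mV),
#'   `fs_hz`, `stim_time_s`, `intensity_ua`, `t_min`.
#' @export
gen_evoked_sweep <- function(model, t_min = NA_real_, seed = NULL,
                             fs_hz = 20000, stim_time_s = 0.005,
                             duration_s = 0.03, intensity_ua = NA_real_) {
  stopifnot(inherits(model, "plasticity_model"))
  if (!is.null(seed)) set.seed(seed)
  f <- potentiation_at(model, t_min)
  m <- model$baseline_slope_mv_ms * f   # mV/ms
  a <- model$baseline_ps_mv * f         # mV
  n <- round(duration_s * fs_hz)
  tau <- ((seq_len(n) - 1) / fs_hz - stim_time_s) * 1000  # ms post stimulus
  v <- numeric(n)
  rise <- tau >= 1 & tau < 3
  v[rise] <- m * (tau[rise] - 1)
  v[tau >= 3 & tau < 4] <- 2 * m
  dip <- tau >= 4 & tau < 8
  v[dip] <- 2 * m - a * sin(pi * (tau[dip] - 4) / 4)^2
  v[tau >= 8 & tau < 9] <- 2 * m
  decay <- tau >= 9 & tau < 19
  v[decay] <- 2 * m * (1 - (tau[decay] - 9) / 10)
  if (model$sweep_noise_frac > 0)
    v <- v * (1 + model$sweep_noise_frac * stats::rnorm(n))
  structure(list(samples = v, fs_hz = fs_hz, stim_time_s = stim_time_s,
                 intensity_ua = intensity_ua, t_min = t_min),
            class = "evoked_sweep")
}

# Per-window amplitude multipliers and per-HFS-epoch coupling depths for the
# three scenario presets. The directions (not magnitudes) encode the study
# phenomenology: decaying LTP, theta/delta/alpha/beta suppression with gamma
# spared, and a coupling drop in the second half of HFS for the treated
# scenarios; persistent LTP, a mild transient theta dip with rebound, a
# transient gamma increase and stable coupling for the control scenario.
scenario_presets <- function() {
  win <- c("pre", "during", "post1", "post2", "post3")
  amp <- function(...) stats::setNames(c(...), win)
  list(
    control = list(
      theta = amp(1, 0.90, 1.10, 1.05, 1.00),
      delta = amp(1, 1, 1, 1, 1),
      alpha = amp(1, 1, 1, 1, 1),
      beta  = amp(1, 1, 1, 1, 1),
      gamma = amp(1, 1.10, 1.05, 1, 1),
      coupling_pre = 0.7,
      coupling_during = rep(0.8, 10),
      coupling_post = 0.7,
      plasticity = plasticity_model(decay_tau_min = Inf,
                                    potentiation_factor = 1.5,
                                    sweep_noise_frac = 0.05)
    ),
    mk801_w1 = list(
      theta = amp(1, 0.60, 0.70, 0.80, 0.90),
      delta = amp(1, 0.70, 0.80, 0.90, 1.00),
      alpha = amp(1, 0.70, 0.80, 0.85, 0.90),
      beta  = amp(1, 0.65, 0.75, 0.85, 0.90),
      gamma = amp(1, 1, 1, 1, 1),
      coupling_pre = 0.7,
      coupling_during = c(rep(0.7, 5), rep(0.35, 5)),
      coupling_post = 0.7,
      plasticity = plasticity_model(decay_tau_min = 240,
                                    potentiation_factor = 1.5,
                                    sweep_noise_frac = 0.05)
    ),
    mk801_w4 = list(
      theta = amp(1, 0.60, 0.65, 0.70, 0.75),
      delta = amp(1, 0.70, 0.75, 0.90, 1.00),
      alpha = amp(1, 0.70, 0.75, 0.80, 0.85),
      beta  = amp(1, 0.65, 0.70, 0.80, 0.85),
      gamma = amp(1, 1, 1, 1, 1),
      coupling_pre = 0.7,
      coupling_during = c(rep(0.7, 5), rep(0.35, 5)),
      coupling_post = 0.7,
      plasticity = plasticity_model(decay_tau_min = 240,
                                    potentiation_factor = 1.4,
                                    sweep_noise_frac = 0.05)
    )
  )
}

#' Generate a complete synthetic experiment
#'
#' Builds a 500 s recording spanning the five analysis windows (100 s
#' pre-HFS, 100 s during HFS with 10 trains at 10 s intervals, three 100 s
#' post-HFS windows), with stimulation artifacts injected, plus the evoked
#' sweep schedule and a plasticity model. Per-window oscillator amplitudes
#' and per-HFS-epoch coupling depths follow the named scenario preset, and
#' are attached as ground truth for recovery tests.
#'
#' @param condition `"control"`, `"mk801_w1"` or `"mk801_w4"`.
#' @param seed Integer seed (required for reproducibility).
#' @param fs_hz Sampling rate (default 2000).
#' @return A list of class `eeg_experiment` with elements `recording`,
#'   `plasticity`, `sweep_times_min` (the evoked-response schedule, minutes
#'   relative to HFS) and `truth`.
#' @export
gen_experiment <- function(condition = c("control", "mk801_w1", "mk801_w4"),
                           seed = 1, fs_hz = 2000) {
  condition <- match.arg(condition)
  preset <- scenario_presets()[[condition]]
  set.seed(seed)
  dur <- 500
  hfs_start <- 100
  n <- dur * fs_hz
  t <- (seq_len(n) - 1) / fs_hz
  base <- list(theta = c(f = 8, a = 100), delta = c(f = 3, a = 40),
               alpha = c(f = 11, a = 25), beta = c(f = 20, a = 20),
               gamma = c(f = 78, a = 30))
  win_of_t <- findInterval(t, c(0, 100, 200, 300, 400)) # 1..5
  # amplitude multiplier as a step function over the five windows
  step_amp <- function(factors) factors[win_of_t]
  theta_phase <- 2 * pi * base$theta["f"] * t
  # coupling depth: per-window, refined to 10 s sub-windows inside `during`
  d_t <- numeric(n)
  d_t[win_of_t == 1] <- preset$coupling_pre
  d_t[win_of_t >= 3] <- preset$coupling_post
  during_idx <- which(win_of_t == 2)
  sub <- pmin(10L, floor((t[during_idx] - hfs_start) / 10) + 1L)
  d_t[during_idx] <- preset$coupling_during[sub]
  phases <- stats::runif(4, 0, 2 * pi)
  sig <- step_amp(preset$theta) * base$theta["a"] * cos(theta_phase) +
    step_amp(preset$delta) * base$delta["a"] *
      cos(2 * pi * base$delta["f"] * t + phases[1]) +
    step_amp(preset$alpha) * base$alpha["a"] *
      cos(2 * pi * base$alpha["f"] * t + phases[2]) +
    step_amp(preset$beta) * base$beta["a"] *
      cos(2 * pi * base$beta["f"] * t + phases[3]) +
    step_amp(preset$gamma) * base$gamma["a"] * (1 + d_t * cos(theta_phase)) *
      cos(2 * pi * base$gamma["f"] * t + phases[4]) +
    gen_pink_noise(n, fs_hz, alpha = 1, rms_uv = 20) +
    10 * sin(2 * pi * 50 * t)
  schedule <- gen_stim_schedule(n_hfs_trains = 10, train_interval_s = 10,
                                tp_rate_hz = 0.025, duration_s = dur,
                                hfs_start_s = hfs_start)
  rec <- recording(sig, fs_hz = fs_hz, condition = condition,
                   subject_id = sprintf("synth-%d", seed))
  rec <- inject_artifacts(rec, schedule, artifact_amp_uv = 10 * sqrt(mean(sig^2)))
  truth <- list(condition = condition, oscillators = base,
                window_amp = preset[c("theta", "delta", "alpha", "beta", "gamma")],
                coupling_pre = preset$coupling_pre,
                coupling_during = preset$coupling_during,
                coupling_post = preset$coupling_post,
                plasticity = unclass(preset$plasticity),
                decay_tau = preset$plasticity$decay_tau_min,
                seed = seed)
  rec$truth <- truth
  structure(list(recording = rec, plasticity = preset$plasticity,
                 sweep_times_min = ltp_schedule(), truth = truth),
            class = "eeg_experiment")
}

#' The evoked-response recording schedule
#'
#' Six baseline points at 5 min intervals, then three post-HFS points at
#' 5 min intervals, 15 min intervals out to 4 h, and a final block at
#' 24-25 h.
#' @return Numeric vector of time points in minutes relative to HFS
#'   (negative = baseline).
#' @export
ltp_schedule <- function() {
  c(seq(-30, -5, by = 5),       # 6 baseline points
    c(5, 10, 15),               # first three post-HFS points
    seq(30, 240, by = 15),      # 15 min intervals to 4 h
    seq(1440, 1485, by = 15))   # 24-25 h block
}
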