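# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the analytic signal comes from the textbook FFT
# construction, band-passing from signal::butter, and epoch search from a
# literal scan over every candidate start.

# analytic signal via the FFT half-spectrum construction
hilbert_fft <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Butterworth band-pass matched to a Morlet filter's half-power bandwidth
butter_bandpass <- function(x, fs, fc, width = 7, order = 2) {
  hw <- fc / width * sqrt(log(2)) * sqrt(2)  # match Gaussian -3 dB points
  bf <- signal::butter(order, c(fc - hw, fc + hw) / (fs / 2), "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# brute-force ESC oracle: band-pass + Hilbert envelope + Pearson
oracle_esc <- function(x, fs, f_lo, f_hi, trim) {
  xl <- butter_bandpass(x, fs, f_lo)
  xh <- butter_bandpass(x, fs, f_hi)
  env <- Mod(hilbert_fft(xh))
  idx <- (trim + 1):(length(x) - trim)
  stats::cor(xl[idx], env[idx])
}

# literal earliest-clean-run scan (quadratic, independent of rle logic)
brute_earliest_clean <- function(mask_seg, n_ep) {
  last <- length(mask_seg) - n_ep + 1L
  if (last < 1L) return(NA_integer_)
  for (j in seq_len(last))
    if (!any(mask_seg[j:(j + n_ep - 1L)])) return(j)
  NA_integer_
}

# random artifact layout over n samples: a few intervals of varied length
random_mask <- function(n, n_art, max_len, rng_seed) {
  set.seed(rng_seed)
  mask <- rep(FALSE, n)
  for (i in seq_len(n_art)) {
    a <- sample.int(n, 1)
    len <- sample.int(max_len, 1)
    mask[a:min(n, a + len - 1L)] <- TRUE
  }
  mask
}

# a theta-gamma coupled test signal plus its morlet-filtered theta series
# and gamma envelope, trimmed for correlation
coupled_series <- function(depth, seed, noise = 20, fs = 2000, dur = 4.1,
                           lag = 0) {
  cfg <- synth_config(dur, fs_hz = fs, coupling_depth = depth,
                      coupling_phase_lag = lag, noise_amp_uv = noise,
                      line_amp_uv = 0, seed = seed)
  r <- gen_coupled_eeg(cfg)
  fl <- morlet_filter(r$samples, fs, 8)
  fh <- morlet_filter(r$samples, fs, 78)
  trim <- ceiling(morlet_sigma_t(8) * fs)
  idx <- (trim + 1):(length(r$samples) - trim)
  list(x = Re(fl)[idx], y = Mod(fh)[idx], samples = r$samples, fs = fs)
}
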