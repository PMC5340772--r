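#' Canonical frequency-band definitions
#'
#' Delta 2-4, theta 4-10, alpha 10-12, beta 12-28 and gamma 30-100 Hz. Band
#' membership downstream is half-open `[f_low, f_high)`, which makes the
#' shared delta/theta and theta/alpha endpoints unambiguous.
#'
#' @return Data frame with columns `name`, `f_low`, `f_high`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             f_low = c(2, 4, 10, 12, 30),
             f_high = c(4, 10, 12, 28, 100),
             stringsAsFactors = FALSE)
}

#' Zero-phase IIR notch (band-stop) filter for mains-line removal
#'
#' Butterworth band-stop designed with -3 dB edges at `f_low` and `f_high`
#' (defaults 48.5 and 55 Hz), applied forward-backward
#' ([signal::filtfilt()]) so the net phase distortion is zero — the
#' phase-amplitude coupling stage downstream is phase-sensitive. Output
#' length equals input length.
#'
#' @param samples Numeric signal (or an `eeg_epoch`).
#' @param fs_hz Sampling rate; taken from the epoch if one is given.
#' @param f_low,f_high Stop-band -3 dB edges in Hz.
#' @param order Butterworth prototype order (default 2, i.e. a 4th-order
#'   band-stop).
#' @return Filtered signal (numeric), or the epoch with filtered samples.
#' @export
notch_filter <- function(samples, fs_hz = NULL, f_low = 48.5, f_high = 55,
                         order = 2) {
  if (inherits(samples, "eeg_epoch")) {
    samples$samples <- notch_filter(samples$samples, samples$fs_hz,
                                    f_low, f_high, order)
    return(samples)
  }
  if (is.null(fs_hz)) stop("fs_hz required")
  if (fs_hz <= 2 * f_high)
    stop(sprintf("sampling rate %g Hz too low for a %g-%g Hz band-stop",
                 fs_hz, f_low, f_high))
  bf <- signal::butter(order, c(f_low, f_high) * 2 / fs_hz, type = "stop")
  as.numeric(signal::filtfilt(bf, samples))
}

#' Welch power spectrum on an NFFT grid
#'
#' Hann-tapered, 50%-overlapping segment averaging with FFT length `nfft`
#' (design value 2048). Power is returned per one-sided frequency bin,
#' scaled so that the sum over bins equals the signal variance (Parseval
#' consistency, up to windowing loss). Signals shorter than `nfft` are
#' analyzed as a single zero-padded segment.
#'
#' @param samples Numeric signal or an `eeg_epoch`.
#' @param fs_hz Sampling rate; taken from the epoch if one is given.
#' @param nfft FFT length (> 0).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @return Object of class `power_spectrum` with fields `freqs` (Hz),
#'   `power` (uV^2 per bin), `nfft`, `fs_hz`, `n_segments`.
#' @export
power_spectrum <- function(samples, fs_hz = NULL, nfft = 2048, overlap = 0.5) {
  if (inherits(samples, "eeg_epoch")) {
    fs_hz <- samples$fs_hz
    samples <- samples$samples
  }
  if (is.null(fs_hz)) stop("fs_hz required")
  if (nfft <= 0) stop("nfft must be a positive integer")
  n <- length(samples)
  if (n == 0) stop("empty signal")
  x <- samples - mean(samples)
  seg_len <- min(nfft, n)
  w <- signal::hanning(seg_len)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  n_bins <- floor(nfft / 2) + 1L
  acc <- numeric(n_bins)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    if (seg_len < nfft) seg <- c(seg, numeric(nfft - seg_len))
    X <- stats::fft(seg)[seq_len(n_bins)]
    acc <- acc + (Mod(X)^2)
  }
  scale <- 2 / (sum(w^2) * nfft)
  p <- acc / length(starts) * scale
  p[1] <- p[1] / 2                                  # DC is not doubled
  if (nfft %% 2 == 0) p[n_bins] <- p[n_bins] / 2    # nor is Nyquist
  structure(list(freqs = (seq_len(n_bins) - 1L) * fs_hz / nfft,
                 power = p, nfft = nfft, fs_hz = fs_hz,
                 n_segments = length(starts)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins to %.1f Hz (df = %.3f Hz, %d segment%s)\n",
              length(x$freqs), max(x$freqs), x$fs_hz / x$nfft, x$n_segments,
              if (x$n_segments == 1) "" else "s"))
  invisible(x)
}

#' Mean power in a frequency band
#'
#' Mean of the spectrum bins with `f_low <= f < f_high` (half-open).
#'
#' @param spectrum A [power_spectrum()].
#' @param band One row of [band_definitions()] or a list with `name`,
#'   `f_low`, `f_high`.
#' @return Mean bin power (uV^2).
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sel <- spectrum$freqs >= band$f_low & spectrum$freqs < band$f_high
  if (!any(sel))
    stop(sprintf("band %s (%g-%g Hz) contains no spectrum bins",
                 band$name, band$f_low, band$f_high))
  mean(spectrum$power[sel])
}

#' Baseline-relative power
#'
#' Expresses band powers as a percentage of the matching baseline (pre-HFS)
#' band powers: `100 * power / baseline`.
#'
#' @param powers Named numeric vector of band powers.
#' @param baseline_powers Named numeric vector of baseline band powers over
#'   the same bands.
#' @return Named numeric vector of percentages.
#' @export
relative_power <- function(powers, baseline_powers) {
  stopifnot(all(names(powers) %in% names(baseline_powers)))
  base <- baseline_powers[names(powers)]
  zero <- names(base)[base <= 0]
  if (length(zero))
    stop("zero baseline power in band(s): ", paste(zero, collapse = ", "))
  100 * powers / base
}

#' Band-power table across the five analysis windows
#'
#' For every window, each epoch is (optionally) notch-filtered, its Welch
#' spectrum computed, and band powers averaged across the window's epochs
#' (epoch-mean of band powers). Relative power is the window mean expressed
#' as a percentage of the `pre` window mean, per band — so the `pre` row is
#' 100% by construction.
#'
#' @param epochs_by_window Named list (window label -> list of `eeg_epoch`),
#'   as returned by [extract_all_epochs()]; must contain `"pre"`.
#' @param bands Band definitions (default [band_definitions()]).
#' @param nfft FFT length (default 2048).
#' @param notch Apply the mains notch first (default TRUE).
#' @return Data frame with columns `window_label`, `band_name`,
#'   `absolute_power`, `relative_power_pct`.
#' @export
band_power_table <- function(epochs_by_window, bands = band_definitions(),
                             nfft = 2048, notch = TRUE) {
  if (!"pre" %in% names(epochs_by_window))
    stop("epochs_by_window must contain a 'pre' (baseline) window")
  win_means <- lapply(epochs_by_window, function(eps) {
    per_epoch <- vapply(eps, function(ep) {
      if (notch) ep <- notch_filter(ep)
      sp <- power_spectrum(ep, nfft = nfft)
      vapply(seq_len(nrow(bands)), function(b) band_power(sp, bands[b, ]),
             numeric(1))
    }, numeric(nrow(bands)))
    rowMeans(matrix(per_epoch, nrow = nrow(bands)))
  })
  base <- stats::setNames(win_means[["pre"]], bands$name)
  do.call(rbind, lapply(names(win_means), function(wl) {
    abs_p <- stats::setNames(win_means[[wl]], bands$name)
    data.frame(window_label = wl, band_name = bands$name,
               absolute_power = unname(abs_p),
               relative_power_pct = unname(relative_power(abs_p, base)),
               stringsAsFactors = FALSE)
  }))
}

#' Per-frequency theta profile relative to baseline
#'
#' Power at the individual theta frequencies (5-10 Hz by default): for each
#' integer frequency, the mean of spectrum bins within `half_width_hz` of
#' it, averaged over a window's epochs and expressed as a percentage of the
#' same frequency's `pre`-window value.
#'
#' @inheritParams band_power_table
#' @param frequencies Integer frequencies in Hz (default 5:10).
#' @param half_width_hz Bin-selection half width (default 0.5 Hz; requires
#'   spectrum resolution `fs / nfft` <= 1 Hz).
#' @return Data frame with columns `window_label`, `freq_hz`,
#'   `absolute_power`, `relative_power_pct`.
#' @export
theta_profile <- function(epochs_by_window, frequencies = 5:10,
                          nfft = 2048, half_width_hz = 0.5, notch = TRUE) {
  if (!"pre" %in% names(epochs_by_window))
    stop("epochs_by_window must contain a 'pre' (baseline) window")
  fs <- epochs_by_window[["pre"]][[1]]$fs_hz
  if (fs / nfft > 2 * half_width_hz + 1e-9)
    stop("spectrum resolution coarser than the per-frequency bin width; increase nfft")
  win_means <- lapply(epochs_by_window, function(eps) {
    per_epoch <- vapply(eps, function(ep) {
      if (notch) ep <- notch_filter(ep)
      sp <- power_spectrum(ep, nfft = nfft)
      vapply(frequencies, function(f0) {
        sel <- abs(sp$freqs - f0) <= half_width_hz
        mean(sp$power[sel])
      }, numeric(1))
    }, numeric(length(frequencies)))
    rowMeans(matrix(per_epoch, nrow = length(frequencies)))
  })
  base <- win_means[["pre"]]
  zero <- frequencies[base <= 0]
  if (length(zero))
    stop("zero baseline power at ", paste(zero, collapse = ", "), " Hz")
  do.call(rbind, lapply(names(win_means), function(wl) {
    data.frame(window_label = wl, freq_hz = frequencies,
               absolute_power = win_means[[wl]],
               relative_power_pct = 100 * win_means[[wl]] / base,
               stringsAsFactors = FALSE)
  }))
}
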