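#' Frequency-bin grid for comodulograms
#'
#' The full grid spans 3-98 Hz in 5 Hz increments (20 center frequencies,
#' each representing a +/- 2 Hz bin); the gamma grid spans 33-98 Hz
#' (14 centers).
#'
#' @param range `"full"` or `"gamma"`.
#' @return List with `centers` (Hz) and `half_width_hz` (2).
#' @export
frequency_grid <- function(range = c("full", "gamma")) {
  range <- match.arg(range)
  centers <- switch(range, full = seq(3, 98, by = 5), gamma = seq(33, 98, by = 5))
  list(centers = centers, half_width_hz = 2)
}

#' Complex Morlet wavelet filter
#'
#' Band-selective analytic filtering: the signal spectrum is multiplied by a
#' Gaussian centered on `center_freq_hz` with frequency-domain standard
#' deviation `center_freq_hz / width_cycles` (the classic Morlet of
#' `width_cycles` cycles), negative frequencies are zeroed, and the result
#' transformed back. This full-length FFT convolution is numerically
#' equivalent to time-domain convolution with the complex Morlet wavelet up
#' to edge handling; callers that correlate envelopes trim one wavelet
#' standard deviation (`morlet_sigma_t()`) from each end. The magnitude of
#' the output is the instantaneous amplitude, its argument the
#' instantaneous phase; a unit sinusoid at the center frequency yields an
#' envelope of 1.
#'
#' @param samples Numeric signal.
#' @param fs_hz Sampling rate (Hz).
#' @param center_freq_hz Filter center frequency (Hz, < Nyquist).
#' @param width_cycles Wavelet width in cycles (default 7).
#' @return Complex vector of the same length as `samples`.
#' @export
morlet_filter <- function(samples, fs_hz, center_freq_hz, width_cycles = 7) {
  stopifnot(is.numeric(samples), fs_hz > 0, width_cycles > 0)
  if (center_freq_hz >= fs_hz / 2)
    stop(sprintf("center frequency %g Hz is at or above Nyquist (%g Hz)",
                 center_freq_hz, fs_hz / 2))
  if (center_freq_hz <= 0) stop("center frequency must be > 0")
  n <- length(samples)
  f <- (seq_len(n) - 1) * fs_hz / n
  sigma_f <- center_freq_hz / width_cycles
  H <- numeric(n)
  pos <- f <= fs_hz / 2
  # one-sided (analytic) response: doubled positive frequencies, zero
  # negatives, so a unit sinusoid at the center yields unit envelope
  H[pos] <- 2 * exp(-(f[pos] - center_freq_hz)^2 / (2 * sigma_f^2))
  H[1] <- 0  # no DC
  if (n %% 2 == 0) H[n / 2 + 1] <- H[n / 2 + 1] / 2
  stats::fft(stats::fft(samples) * H, inverse = TRUE) / n
}

#' Temporal standard deviation of a Morlet wavelet
#' @param center_freq_hz Center frequency (Hz).
#' @param width_cycles Width in cycles.
#' @return Wavelet SD in seconds, `width / (2 * pi * f)`.
#' @export
morlet_sigma_t <- function(center_freq_hz, width_cycles = 7) {
  width_cycles / (2 * pi * center_freq_hz)
}

#' Envelope-to-signal correlation (ESC)
#'
#' The raw phase-amplitude coupling score: the Pearson correlation between
#' the low-frequency filtered signal and the amplitude envelope of the
#' high-frequency band. Bounded in `[-1, 1]`; a positive score means the
#' fast envelope peaks on the slow wave's peaks, a negative score on its
#' troughs.
#'
#' @param signal_low Real low-frequency filtered series.
#' @param envelope_high Real high-frequency amplitude envelope, same length.
#' @return Correlation in `[-1, 1]`. If either series is constant the score
#'   is defined as 0 and carries the attribute `degenerate = TRUE`.
#' @export
esc <- function(signal_low, envelope_high) {
  if (length(signal_low) != length(envelope_high))
    stop("series lengths differ")
  if (length(signal_low) < 2) stop("need at least 2 samples")
  if (stats::sd(signal_low) == 0 || stats::sd(envelope_high) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(signal_low, envelope_high)
}

#' Surrogate-normalized ESC score
#'
#' Builds a null distribution by a windowed envelope shuffle: for each of
#' `n_shuffles` surrogates the envelope is cut at `n_blocks - 1` random
#' points and the resulting blocks permuted, the ESC recomputed, and
#' `z = (raw - mean(surrogates)) / sd(surrogates)` returned. The block
#' permutation preserves the envelope's value distribution exactly and its
#' short-range autocorrelation within blocks (so the surrogate spread
#' matches the null sampling variability of the correlation) while
#' destroying the envelope's alignment with the slow phase at the
#' modulation time scale (so genuinely coupled signals score far outside
#' the surrogate distribution). The block length should be several times
#' the envelope's coherence time; [comodulogram()] and friends derive it
#' from the envelope's center frequency.
#'
#' @param raw_esc The observed ESC score (see [esc()]).
#' @param signal_low,envelope_high The series the score was computed from.
#' @param n_shuffles Number of surrogate shuffles (design value 200; >= 2).
#' @param seed Optional integer seed; identical seeds give identical z.
#' @param n_blocks Number of envelope blocks per shuffle (>= 2; default 20).
#' @return Numeric z-score with attributes `raw`, `surrogate_mean`,
#'   `surrogate_sd`. If the surrogate SD is zero the value is `NA` with
#'   attribute `flag = "zero-surrogate-sd"`.
#' @export
surrogate_normalize <- function(raw_esc, signal_low, envelope_high,
                                n_shuffles = 200, seed = NULL,
                                n_blocks = 20) {
  if (n_shuffles < 2) stop("n_shuffles must be >= 2")
  if (length(signal_low) != length(envelope_high))
    stop("series lengths differ")
  n <- length(signal_low)
  n_blocks <- max(2L, min(as.integer(n_blocks), n %/% 2L))
  if (!is.null(seed)) set.seed(seed)
  xc <- signal_low - mean(signal_low)
  y <- envelope_high
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum((y - mean(y))^2))
  if (sx == 0 || sy == 0)
    return(structure(NA_real_, flag = "degenerate-input"))
  xc_s <- xc / (sx * sy)
  # xc is centered, so the permuted envelope's mean term vanishes and the
  # surrogate correlation is a plain weighted sum
  surr <- vapply(seq_len(n_shuffles), function(i) {
    cuts <- sort(sample.int(n - 1L, n_blocks - 1L))
    bounds <- c(0L, cuts, n)
    lens <- diff(bounds)
    perm <- sample.int(n_blocks)
    idx <- sequence(lens[perm], from = bounds[perm] + 1L)
    sum(xc_s * y[idx])
  }, numeric(1))
  m <- mean(surr)
  s <- stats::sd(surr)
  if (s == 0) return(structure(NA_real_, flag = "zero-surrogate-sd"))
  structure((raw_esc - m) / s, raw = raw_esc, surrogate_mean = m,
            surrogate_sd = s)
}

# block length heuristic: ~8 coherence times of a Morlet envelope at f_hi,
# i.e. 8 * width / (2 pi f) ~= 8.9 / f seconds at width 7
surrogate_n_blocks <- function(n, fs_hz, f_hi, width_cycles = 7) {
  block_s <- 8 * width_cycles / (2 * pi * f_hi)
  max(4L, min(n %/% 2L, as.integer(round(n / (block_s * fs_hz)))))
}

# Filter an epoch at each grid center once; returns list of complex series.
morlet_bank <- function(samples, fs_hz, centers, width_cycles = 7) {
  stats::setNames(lapply(centers, function(fc)
    morlet_filter(samples, fs_hz, fc, width_cycles)), as.character(centers))
}

# ESC + surrogate z for one ordered (low, high) pair of filtered series.
# Trims one wavelet SD of the LOW (wider-in-time) filter from each end.
pair_scores <- function(filt_low, filt_high, fs_hz, f_low, f_high,
                        width_cycles, n_shuffles, seed) {
  n <- length(filt_low)
  trim <- ceiling(morlet_sigma_t(f_low, width_cycles) * fs_hz)
  if (n - 2 * trim < 8)
    stop(sprintf("epoch too short for a %g Hz bin after edge trimming", f_low))
  idx <- (trim + 1L):(n - trim)
  x <- Re(filt_low)[idx]
  y <- Mod(filt_high)[idx]
  raw <- esc(x, y)
  nb <- surrogate_n_blocks(length(x), fs_hz, f_high, width_cycles)
  z <- surrogate_normalize(as.numeric(raw), x, y, n_shuffles, seed,
                           n_blocks = nb)
  list(raw = as.numeric(raw), z = as.numeric(z),
       flag = attr(z, "flag") %||% NA_character_)
}

#' ESC comodulogram over a frequency-bin grid
#'
#' For every ordered pair of grid bins with a lower (modulating) center
#' frequency below a higher (envelope-providing) center frequency, computes
#' the surrogate-normalized ESC between the low-bin filtered signal and the
#' high-bin amplitude envelope. Matrix rows index the envelope (faster)
#' bin, columns the signal (slower) bin; cells with row center <= column
#' center are structurally `NA`. Bins whose +/- 2 Hz extent overlaps the
#' mains notch stop-band are computed but listed in `$notch_flagged`.
#'
#' @param epoch An `eeg_epoch`, or a numeric signal (then give `fs_hz`).
#' @param grid A [frequency_grid()] (default the full 3-98 Hz grid).
#' @param n_shuffles Surrogates per pair (default 200).
#' @param seed Optional integer seed (per-pair seeds are derived from it).
#' @param width_cycles Morlet width (default 7).
#' @param fs_hz Sampling rate when `epoch` is a bare numeric vector.
#' @param notch_band Stop-band flagged as line-contaminated (Hz).
#' @return Object of class `comodulogram`: `z` and `raw` matrices
#'   (envelope x signal), `centers`, `n_shuffles`, `notch_flagged`, `flags`.
#' @export
comodulogram <- function(epoch, grid = frequency_grid("full"),
                         n_shuffles = 200, seed = NULL, width_cycles = 7,
                         fs_hz = NULL, notch_band = c(48.5, 55)) {
  if (inherits(epoch, "eeg_epoch")) {
    fs_hz <- epoch$fs_hz
    samples <- epoch$samples
  } else samples <- epoch
  if (is.null(fs_hz)) stop("fs_hz required")
  centers <- grid$centers
  min_len <- 3 / min(centers) + 2 * morlet_sigma_t(min(centers), width_cycles)
  if (length(samples) / fs_hz < min_len)
    stop(sprintf("epoch must span at least %.2f s for the %g Hz bin",
                 min_len, min(centers)))
  bank <- morlet_bank(samples, fs_hz, centers, width_cycles)
  nb <- length(centers)
  zm <- matrix(NA_real_, nb, nb, dimnames = list(env = centers, sig = centers))
  rawm <- zm
  flags <- character(0)
  k <- 0L
  for (lo in seq_len(nb)) {
    for (hi in seq_len(nb)) {
      if (centers[hi] <= centers[lo]) next
      k <- k + 1L
      ps <- pair_scores(bank[[lo]], bank[[hi]], fs_hz, centers[lo],
                        centers[hi], width_cycles, n_shuffles,
                        if (is.null(seed)) NULL else seed + k)
      zm[hi, lo] <- ps$z
      rawm[hi, lo] <- ps$raw
      if (!is.na(ps$flag))
        flags <- c(flags, sprintf("(%g,%g): %s", centers[lo], centers[hi],
                                  ps$flag))
    }
  }
  hw <- grid$half_width_hz
  notch_flagged <- centers[centers + hw > notch_band[1] &
                             centers - hw < notch_band[2]]
  structure(list(z = zm, raw = rawm, centers = centers,
                 n_shuffles = n_shuffles, notch_flagged = notch_flagged,
                 flags = flags),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  peak <- which(x$z == max(x$z, na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat(sprintf("<comodulogram> %d x %d bins, %d surrogates; peak z = %.2f at (env %s Hz, sig %s Hz)\n",
              nrow(x$z), ncol(x$z), x$n_shuffles, max(x$z, na.rm = TRUE),
              rownames(x$z)[peak[1]], colnames(x$z)[peak[2]]))
  invisible(x)
}

#' Pooled theta-gamma coupling score for one epoch
#'
#' Mean of the surrogate-normalized ESC over all (theta-bin, gamma-bin)
#' pairs: theta bins are the full-grid centers inside `theta_band`, gamma
#' bins the 33-98 Hz grid.
#'
#' @inheritParams comodulogram
#' @param theta_band Two-element range selecting theta centers (default
#'   4-10 Hz).
#' @param gamma_centers Gamma bin centers (default 33-98 Hz in 5 Hz steps).
#' @param grid_centers Centers from which theta bins are drawn.
#' @return List with `score_z` (mean z), `score_raw` (mean raw ESC),
#'   `pairs` (per-pair data frame).
#' @export
theta_gamma_score <- function(epoch, theta_band = c(4, 10),
                              gamma_centers = frequency_grid("gamma")$centers,
                              grid_centers = frequency_grid("full")$centers,
                              n_shuffles = 200, seed = NULL,
                              width_cycles = 7, fs_hz = NULL) {
  if (inherits(epoch, "eeg_epoch")) {
    fs_hz <- epoch$fs_hz
    samples <- epoch$samples
  } else samples <- epoch
  if (is.null(fs_hz)) stop("fs_hz required")
  theta_centers <- grid_centers[grid_centers >= theta_band[1] &
                                  grid_centers <= theta_band[2]]
  if (length(theta_centers) == 0) stop("no grid centers inside theta_band")
  bank <- morlet_bank(samples, fs_hz, unique(c(theta_centers, gamma_centers)),
                      width_cycles)
  rows <- list()
  k <- 0L
  for (ft in theta_centers) for (fg in gamma_centers) {
    if (fg <= ft) next
    k <- k + 1L
    ps <- pair_scores(bank[[as.character(ft)]], bank[[as.character(fg)]],
                      fs_hz, ft, fg, width_cycles, n_shuffles,
                      if (is.null(seed)) NULL else seed + k)
    rows[[k]] <- data.frame(theta_hz = ft, gamma_hz = fg,
                            score_raw = ps$raw, score_z = ps$z,
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  list(score_z = mean(pairs$score_z, na.rm = TRUE),
       score_raw = mean(pairs$score_raw, na.rm = TRUE),
       pairs = pairs)
}

#' Theta-gamma coupling time course across the HFS epochs
#'
#' Computes the pooled theta-gamma score for each of the (up to ten) epochs
#' extracted during HFS, and expresses each against the mean score of the
#' pre-HFS baseline epochs. Missing sub-window epochs simply leave gaps in
#' `epoch_index`.
#'
#' @param during_epochs List of `eeg_epoch` from the `during` window.
#' @param baseline_epochs List of `eeg_epoch` from the `pre` window (>= 1).
#' @inheritParams theta_gamma_score
#' @return Object of class `coupling_timecourse`: data frame `epochs` with
#'   columns `epoch_index` (0-9), `score_raw`, `score_z`,
#'   `score_rel_baseline` (% of the baseline mean raw score), plus scalars
#'   `baseline_raw`, `baseline_z`.
#' @export
hfs_coupling_timecourse <- function(during_epochs, baseline_epochs,
                                    theta_band = c(4, 10),
                                    gamma_centers = frequency_grid("gamma")$centers,
                                    n_shuffles = 200, seed = NULL,
                                    width_cycles = 7) {
  if (length(during_epochs) < 2) stop("need at least 2 during-HFS epochs")
  if (length(baseline_epochs) < 1) stop("need baseline epochs")
  score_one <- function(ep, s) theta_gamma_score(
    ep, theta_band = theta_band, gamma_centers = gamma_centers,
    n_shuffles = n_shuffles, seed = s, width_cycles = width_cycles)
  base_scores <- lapply(seq_along(baseline_epochs), function(i)
    score_one(baseline_epochs[[i]],
              if (is.null(seed)) NULL else seed + 10000L + i * 100L))
  baseline_raw <- mean(vapply(base_scores, `[[`, numeric(1), "score_raw"))
  baseline_z <- mean(vapply(base_scores, `[[`, numeric(1), "score_z"))
  rows <- lapply(seq_along(during_epochs), function(i) {
    ep <- during_epochs[[i]]
    sc <- score_one(ep, if (is.null(seed)) NULL else seed + i * 100L)
    data.frame(epoch_index = if (inherits(ep, "eeg_epoch"))
                 ep$sub_window_index else i - 1L,
               score_raw = sc$score_raw, score_z = sc$score_z,
               stringsAsFactors = FALSE)
  })
  epochs <- do.call(rbind, rows)
  epochs$score_rel_baseline <- if (abs(baseline_raw) > 0)
    100 * epochs$score_raw / baseline_raw else NA_real_
  structure(list(epochs = epochs, baseline_raw = baseline_raw,
                 baseline_z = baseline_z),
            class = "coupling_timecourse")
}

#' @export
print.coupling_timecourse <- function(x, ...) {
  cat(sprintf("<coupling_timecourse> %d HFS epochs; baseline raw ESC %.3f (z %.2f)\n",
              nrow(x$epochs), x$baseline_raw, x$baseline_z))
  print(x$epochs, row.names = FALSE)
  invisible(x)
}
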