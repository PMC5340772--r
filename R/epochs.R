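#' Locate the five 100 s analysis windows around HFS
#'
#' The analysis design defines five contiguous 100 s windows: `pre` is the
#' 100 s immediately before the first HFS train, `during` starts at the
#' first train onset (the ten trains at 10 s intervals all fall inside it),
#' and `post1`/`post2`/`post3` follow contiguously.
#'
#' @param recording An `eeg_recording` whose event log contains at least one
#'   `hfs_train`.
#' @param window_s Window duration in seconds (design value 100).
#' @return Data frame with columns `label`, `start_s`, `duration_s` (five
#'   rows, ordered pre / during / post1 / post2 / post3).
#' @export
locate_windows <- function(recording, window_s = 100) {
  stopifnot(inherits(recording, "eeg_recording"))
  hfs <- recording$events[recording$events$kind == "hfs_train", , drop = FALSE]
  if (nrow(hfs) == 0)
    stop("window scheme requires a tetanus: no hfs_train events in the recording")
  onset <- min(hfs$time_s)
  last_end <- max(hfs$time_s + hfs$duration_s)
  if (last_end > onset + window_s)
    stop("HFS trains span more than one during-window; cannot place windows")
  starts <- onset + window_s * (-1:3)
  dur <- recording_duration(recording)
  if (starts[1] < -1e-9)
    stop(sprintf("recording starts %.1f s before HFS; %g s of pre-HFS baseline required",
                 onset, window_s))
  if (starts[5] + window_s > dur + 1e-9)
    stop(sprintf("recording ends %.1f s after HFS onset; %g s required for the post windows",
                 dur - onset, 4 * window_s))
  data.frame(label = c("pre", "during", "post1", "post2", "post3"),
             start_s = starts, duration_s = window_s,
             stringsAsFactors = FALSE)
}

#' Flag artifact samples
#'
#' A sample is flagged if its absolute deviation from the median exceeds
#' `threshold_sd` robust standard deviations (median absolute deviation,
#' scaled), or if it falls inside a declared stimulation-event interval
#' extended by a guard margin on both sides.
#'
#' @param samples Numeric signal.
#' @param fs_hz Sampling rate (Hz).
#' @param events Optional event data frame (`time_s`, `kind`, `duration_s`).
#' @param threshold_sd Amplitude threshold in robust SDs (> 0; default 6).
#' @param guard_s Guard margin around each event in seconds (default 0.05).
#' @return Logical mask of the same length as `samples` (`TRUE` = artifact).
#' @export
detect_artifacts <- function(samples, fs_hz, events = NULL,
                             threshold_sd = 6, guard_s = 0.05) {
  stopifnot(is.numeric(samples), fs_hz > 0)
  if (threshold_sd <= 0) stop("threshold_sd must be > 0")
  med <- stats::median(samples)
  s <- stats::mad(samples)
  mask <- if (s > 0) abs(samples - med) > threshold_sd * s
          else rep(FALSE, length(samples))
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      a <- max(1L, floor((events$time_s[i] - guard_s) * fs_hz) + 1L)
      b <- min(length(samples),
               ceiling((events$time_s[i] + events$duration_s[i] + guard_s) * fs_hz) + 1L)
      if (a <= b) mask[a:b] <- TRUE
    }
  }
  mask
}

new_epoch <- function(samples, fs_hz, window_label, sub_window_index, start_s) {
  structure(list(samples = samples, fs_hz = fs_hz,
                 window_label = window_label,
                 sub_window_index = sub_window_index, start_s = start_s),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s[%d] start %.3f s, %.2f s @ %g Hz\n",
              x$window_label, x$sub_window_index, x$start_s,
              length(x$samples) / x$fs_hz, x$fs_hz))
  invisible(x)
}

#' Extract artifact-free epochs from one analysis window
#'
#' The 100 s window is split into ten 10 s sub-windows; from each, the
#' earliest run of `epoch_s` seconds of entirely unflagged samples is
#' returned (deterministic earliest-run tie-break). Sub-windows containing
#' no clean run of sufficient length contribute nothing (reported via
#' `message()`); if no sub-window yields an epoch the call errors.
#'
#' @param recording An `eeg_recording`.
#' @param window One row of [locate_windows()] output (or a list with
#'   `label`, `start_s`, `duration_s`).
#' @param mask Logical artifact mask over the whole recording, as returned
#'   by [detect_artifacts()].
#' @param epoch_s Epoch length in seconds (design value 4.1).
#' @param sub_window_s Sub-window length in seconds (design value 10).
#' @return List of `eeg_epoch` objects (at most
#'   `duration_s / sub_window_s`), with `sub_window_index` 0-based.
#' @export
extract_epochs <- function(recording, window, mask, epoch_s = 4.1,
                           sub_window_s = 10) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs_hz
  x <- recording$samples
  if (length(mask) != length(x))
    stop("mask length must equal the number of samples")
  w_start <- window$start_s
  w_dur <- window$duration_s
  if (w_start < -1e-9 || (w_start + w_dur) * fs > length(x) + 1e-6)
    stop("window must lie fully inside the recording")
  n_ep <- round(epoch_s * fs)
  n_sub <- floor(w_dur / sub_window_s)
  out <- list()
  for (i in seq_len(n_sub) - 1L) {
    a <- floor((w_start + i * sub_window_s) * fs) + 1L
    b <- min(length(x), floor((w_start + (i + 1) * sub_window_s) * fs))
    j <- earliest_clean_start(mask[a:b], n_ep)
    if (is.na(j)) {
      message(sprintf("sub-window %d of %s window: no %.1f s artifact-free run",
                      i, window$label, epoch_s))
      next
    }
    idx <- (a + j - 1L):(a + j - 2L + n_ep)
    out[[length(out) + 1L]] <- new_epoch(x[idx], fs, window$label, i,
                                         (a + j - 2L) / fs)
  }
  if (length(out) == 0)
    stop(sprintf("no artifact-free %.1f s epoch found in any sub-window of the %s window",
                 epoch_s, window$label))
  out
}

# first index (1-based, within the segment) where a run of n_ep consecutive
# FALSE values begins, or NA
earliest_clean_start <- function(mask_seg, n_ep) {
  if (n_ep > length(mask_seg)) return(NA_integer_)
  r <- rle(mask_seg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(!r$values & r$lengths >= n_ep)
  if (length(ok) == 0) return(NA_integer_)
  starts[ok[1]]
}

#' Extract epochs for all five analysis windows
#'
#' Convenience wrapper: locates windows, computes the artifact mask over the
#' whole recording, and extracts epochs per window.
#'
#' @inheritParams extract_epochs
#' @inheritParams detect_artifacts
#' @return Named list (window label -> list of `eeg_epoch`).
#' @export
extract_all_epochs <- function(recording, epoch_s = 4.1, sub_window_s = 10,
                               threshold_sd = 6, guard_s = 0.05) {
  wins <- locate_windows(recording)
  mask <- detect_artifacts(recording$samples, recording$fs_hz,
                           recording$events, threshold_sd, guard_s)
  out <- lapply(seq_len(nrow(wins)), function(i)
    extract_epochs(recording, wins[i, ], mask, epoch_s, sub_window_s))
  names(out) <- wins$label
  out
}

#' Down-sample a recording with anti-alias filtering
#'
#' Decimates by an integer factor after an anti-alias low-pass
#' (via [signal::decimate()]). Events are preserved unchanged. Refuses to
#' down-sample below twice the highest frequency the analysis needs.
#'
#' @param recording An `eeg_recording`.
#' @param target_fs_hz Target sampling rate; must divide the current rate.
#' @param analysis_top_hz Highest frequency of interest downstream (default
#'   100, the top of the gamma band).
#' @return A new `eeg_recording` at `target_fs_hz`.
#' @export
downsample <- function(recording, target_fs_hz, analysis_top_hz = 100) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs_hz
  if (target_fs_hz <= 2 * analysis_top_hz)
    stop(sprintf("target rate %g Hz violates the Nyquist margin for a %g Hz analysis band",
                 target_fs_hz, analysis_top_hz))
  if (target_fs_hz > fs) stop("target rate exceeds the current rate")
  q <- fs / target_fs_hz
  if (abs(q - round(q)) > 1e-9)
    stop("target rate must divide the current sampling rate")
  q <- as.integer(round(q))
  if (q == 1L) return(recording)
  out <- recording
  out$samples <- as.numeric(signal::decimate(recording$samples, q, ftype = "fir"))
  out$fs_hz <- target_fs_hz
  out
}
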