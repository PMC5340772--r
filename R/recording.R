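#' Construct a continuous EEG/LFP recording
#'
#' A recording bundles a regularly sampled single-channel signal (microvolts)
#' with its sampling rate, a stimulation-event log, and labels. This is the
#' container every downstream stage (windowing, epoching, spectra, coupling)
#' consumes.
#'
#' @param samples Numeric vector, the signal in microvolts.
#' @param fs_hz Sampling rate in samples/second (default 2000, the rate the
#'   acquisition design uses).
#' @param events Data frame of stimulation events with columns `time_s`,
#'   `kind` (one of `"test_pulse"`, `"hfs_train"`) and `duration_s`. May have
#'   zero rows.
#' @param condition Condition label (e.g. `"control"`, `"mk801_w1"`).
#' @param subject_id Subject label.
#' @param truth Optional list of ground-truth generator parameters, attached
#'   by the synthetic generator so recovery tests can compare estimates
#'   against what was simulated.
#' @return An object of class `eeg_recording`.
#' @seealso [stim_event()], [gen_coupled_eeg()], [locate_windows()]
#' @export
recording <- function(samples, fs_hz = 2000, events = empty_events(),
                      condition = NA_character_, subject_id = NA_character_,
                      truth = NULL) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop("fs_hz must be a single positive number")
  events <- validate_events(events)
  dur <- length(samples) / fs_hz
  if (nrow(events) > 0) {
    span <- max(events$time_s + events$duration_s)
    if (span > dur + 1e-9)
      stop(sprintf("event log spans %.3f s but the recording lasts only %.3f s",
                   span, dur))
  }
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz, events = events,
                 condition = condition, subject_id = subject_id, truth = truth),
            class = "eeg_recording")
}

#' Construct a stimulation event
#'
#' @param time_s Event onset in seconds from recording start (>= 0).
#' @param kind `"test_pulse"` or `"hfs_train"`.
#' @param duration_s Event duration in seconds.
#' @return One-row data frame with columns `time_s`, `kind`, `duration_s`.
#' @export
stim_event <- function(time_s, kind = c("test_pulse", "hfs_train"),
                       duration_s) {
  kind <- match.arg(kind)
  if (time_s < 0) stop("time_s must be >= 0")
  if (duration_s < 0) stop("duration_s must be >= 0")
  data.frame(time_s = time_s, kind = kind, duration_s = duration_s,
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(time_s = numeric(0), kind = character(0),
             duration_s = numeric(0), stringsAsFactors = FALSE)
}

validate_events <- function(events) {
  if (!is.data.frame(events) ||
      !all(c("time_s", "kind", "duration_s") %in% names(events)))
    stop("events must be a data frame with columns time_s, kind, duration_s")
  if (nrow(events) > 0) {
    if (any(events$time_s < 0)) stop("event time_s must be >= 0")
    bad <- setdiff(unique(events$kind), c("test_pulse", "hfs_train"))
    if (length(bad))
      stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  }
  events[order(events$time_s), , drop = FALSE]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %.1f s @ %g Hz (%d samples)\n",
              length(x$samples) / x$fs_hz, x$fs_hz, length(x$samples)))
  cat(sprintf("  condition: %s  subject: %s\n", x$condition, x$subject_id))
  if (nrow(x$events) > 0) {
    tab <- table(x$events$kind)
    cat("  events:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
        "\n")
  } else cat("  events: none\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An `eeg_recording`.
#' @return Length of the signal divided by the sampling rate, in seconds.
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  length(recording$samples) / recording$fs_hz
}

#' Write a recording as a two-file pair
#'
#' The signal is written as a single-column plain-text file (`<stem>.signal.txt`,
#' microvolts, one sample per line) and everything else (sampling rate, labels,
#' event log, ground-truth parameters) as a YAML sidecar (`<stem>.meta.yaml`).
#'
#' @param recording An `eeg_recording`.
#' @param stem Path stem; the two suffixes are appended.
#' @return Invisibly, the two file paths.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "eeg_recording"))
  sig_path <- paste0(stem, ".signal.txt")
  meta_path <- paste0(stem, ".meta.yaml")
  data.table::fwrite(list(uv = recording$samples), sig_path, col.names = FALSE)
  meta <- list(
    fs_hz = recording$fs_hz,
    condition = recording$condition,
    subject_id = recording$subject_id,
    events = if (nrow(recording$events)) unname(split(recording$events,
                                                      seq_len(nrow(recording$events)))) else list(),
    truth = recording$truth
  )
  meta$events <- lapply(meta$events, function(e)
    list(time_s = e$time_s, kind = e$kind, duration_s = e$duration_s))
  yaml::write_yaml(meta, meta_path)
  invisible(c(signal = sig_path, meta = meta_path))
}

#' Read a recording written by [write_recording()]
#' @param stem Path stem used when writing.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(stem) {
  sig_path <- paste0(stem, ".signal.txt")
  meta_path <- paste0(stem, ".meta.yaml")
  if (!file.exists(sig_path) || !file.exists(meta_path))
    stop("missing ", sig_path, " or ", meta_path)
  x <- data.table::fread(sig_path, header = FALSE)[[1]]
  meta <- yaml::read_yaml(meta_path)
  ev <- if (length(meta$events)) {
    do.call(rbind, lapply(meta$events, function(e)
      data.frame(time_s = e$time_s, kind = e$kind, duration_s = e$duration_s,
                 stringsAsFactors = FALSE)))
  } else empty_events()
  recording(x, fs_hz = meta$fs_hz, events = ev,
            condition = meta$condition %||% NA_character_,
            subject_id = meta$subject_id %||% NA_character_,
            truth = meta$truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
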