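#' fEPSP slope of an evoked sweep
#'
#' Maximum slope of a sliding linear fit (1 ms span) over the initial
#' rising phase of the field EPSP, i.e. between the stimulus and the first
#' post-stimulus peak, reported in mV/ms. The sweep is lightly smoothed
#' (moving average) before fitting, and candidate windows are restricted to
#' the interior of the rise (window values between 5% and 95% of the first
#' peak) so the estimate is stable under sweep noise; interior windows on a
#' linear rise recover the slope exactly.
#'
#' @param sweep An `evoked_sweep` (fields `samples` in mV, `fs_hz`,
#'   `stim_time_s`).
#' @param fit_span_ms Sliding-fit span in ms (default 1).
#' @param smooth_ms Moving-average span in ms (default 0.4).
#' @return Slope in mV/ms.
#' @export
fepsp_slope <- function(sweep, fit_span_ms = 1, smooth_ms = 0.4) {
  stopifnot(inherits(sweep, "evoked_sweep"))
  fs <- sweep$fs_hz
  v <- smooth_ma(sweep$samples, max(1L, round(smooth_ms / 1000 * fs)))
  i0 <- round(sweep$stim_time_s * fs) + 1L
  post <- v[i0:length(v)]
  pks <- evoked_peaks(post)
  if (length(pks) == 0 || post[pks[1]] <= 0)
    stop("no rising phase found after the stimulus")
  p1 <- pks[1]
  w <- max(2L, round(fit_span_ms / 1000 * fs))
  if (p1 <= w) stop("rising phase shorter than the fit span")
  starts <- seq_len(p1 - w + 1L)
  peak_val <- post[p1]
  interior <- post[starts] > 0.05 * peak_val &
    post[starts + w - 1L] < 0.95 * peak_val
  if (any(interior)) starts <- starts[interior]
  tt <- (seq_len(w) - 1) / fs * 1000   # ms
  tc <- tt - mean(tt)
  st <- sum(tc^2)
  slopes <- vapply(starts, function(s)
    sum(tc * post[s:(s + w - 1L)]) / st, numeric(1))
  mx <- max(slopes)
  if (mx <= 0) stop("no rising phase found after the stimulus")
  mx
}

#' Population-spike amplitude of an evoked sweep
#'
#' Amplitude of the negative-going population spike by the standard tangent
#' method: the vertical distance from the straight line joining the two
#' positive peaks flanking the spike down to the spike minimum. Peak and
#' minimum values are taken as short local means of the smoothed sweep so
#' the measure is stable under sweep noise.
#'
#' @inheritParams fepsp_slope
#' @param smooth_ms Moving-average span in ms (default 0.25).
#' @return Amplitude in mV.
#' @export
ps_amplitude <- function(sweep, smooth_ms = 0.25) {
  stopifnot(inherits(sweep, "evoked_sweep"))
  fs <- sweep$fs_hz
  v <- smooth_ma(sweep$samples, max(1L, round(smooth_ms / 1000 * fs)))
  i0 <- round(sweep$stim_time_s * fs) + 1L
  post <- v[i0:length(v)]
  pks <- evoked_peaks(post)
  if (length(pks) == 0 || post[pks[1]] <= 0)
    stop("no evoked response after the stimulus")
  if (length(pks) < 2)
    stop("no population spike: no second positive peak flanking a minimum")
  p1 <- pks[1]
  p2 <- pks[2]
  seg <- post[p1:p2]
  mn <- which.min(seg)
  if (mn == 1L || mn == length(seg))
    stop("no local minimum between the flanking positive peaks")
  mn <- p1 + mn - 1L
  k <- max(1L, round(0.5 / 1000 * fs))       # 0.5 ms shoulder mean
  v1 <- mean(post[max(1L, p1 - k + 1L):p1])  # shoulder precedes peak 1
  v2 <- mean(post[max(1L, p2 - k + 1L):p2])  # ... and peak 2
  k2 <- max(2L, round(0.3 / 1000 * fs))
  vmin <- quad_center_value(post, mn, k2)
  tangent <- v1 + (v2 - v1) * (mn - p1) / (p2 - p1)
  amp <- tangent - vmin
  if (amp <= 0) stop("no population spike: tangent amplitude not positive")
  amp
}

# local quadratic fit around index i: estimates the extremum value from the
# parabola vertex, which is insensitive to a few samples of jitter in the
# located extremum and free of the flattening bias a window mean would add
quad_center_value <- function(x, i, k) {
  a <- max(1L, i - k)
  b <- min(length(x), i + k)
  j <- (a:b) - i
  y <- x[a:b]
  co <- unname(stats::lm.fit(cbind(1, j, j^2), y)$coefficients)
  vertex_drop <- co[2]^2 / (4 * co[3])
  if (is.finite(vertex_drop) && abs(vertex_drop) < diff(range(y)) + 1e-12)
    co[1] - vertex_drop
  else co[1]
}

# centered moving average, edges padded by replication
smooth_ma <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  xp <- c(rep(x[1], k), x, rep(x[n], k))
  cs <- cumsum(c(0, xp))
  lo <- floor((k - 1) / 2)
  hi <- k - 1L - lo
  i <- (k + 1L):(k + n)
  (cs[i + hi + 1L] - cs[i - lo]) / k
}

# Prominence-grouped positive peaks of a post-stimulus waveform: local
# maxima above min_frac of the global max, merged into one peak unless the
# valley between them drops by more than sep_frac of the global max.
# Each group is represented by its LAST candidate (the trailing edge of a
# plateau-shaped peak), so the flanking-shoulder means read from the flat
# top rather than the preceding rise. Indices returned in time order.
evoked_peaks <- function(x, min_frac = 0.5, sep_frac = 0.15) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  mx <- max(x)
  if (mx <= 0) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  cand <- cand[x[cand] >= min_frac * mx]
  if (length(cand) == 0) return(integer(0))
  tol <- 0.5 * sep_frac * mx   # candidates this close to a group's top
                               # still count as part of its flat crown
  reps <- cand[1]
  gmax <- x[cand[1]]
  for (c_i in cand[-1]) {
    prev <- reps[length(reps)]
    valley <- min(x[prev:c_i])
    if (min(gmax, x[c_i]) - valley > sep_frac * mx) {
      reps <- c(reps, c_i)                 # genuinely separate peak
      gmax <- x[c_i]
    } else {
      gmax <- max(gmax, x[c_i])
      if (x[c_i] >= gmax - tol)
        reps[length(reps)] <- c_i          # trailing crown candidate
    }
  }
  reps
}

#' Select the stimulation intensity from an input-output curve
#'
#' Returns the tested intensity whose response magnitude is closest to 40%
#' of the maximum response across the input-output assessment; ties go to
#' the lower intensity. Intensities are tested discretely (100-900 uA in
#' 100 uA steps in the standard protocol), so no interpolation is done.
#'
#' @param responses Named numeric vector: names are intensities in uA,
#'   values the response magnitudes (>= 0). At least two intensities.
#' @param target_frac Fraction of the maximum (default 0.4).
#' @return The selected intensity in uA (numeric).
#' @export
io_select_intensity <- function(responses, target_frac = 0.4) {
  if (length(responses) < 2) stop("need at least two tested intensities")
  if (any(responses < 0)) stop("responses must be non-negative")
  if (all(responses == 0)) stop("all responses are zero; no i/o curve")
  intens <- as.numeric(names(responses))
  if (any(is.na(intens))) stop("responses must be named by intensity (uA)")
  target <- target_frac * max(responses)
  d <- abs(responses - target)
  cand <- intens[d == min(d)]
  min(cand)
}

#' Measure a set of evoked sweeps
#'
#' @param sweeps List of `evoked_sweep` objects.
#' @return Data frame with columns `t_min`, `fepsp_slope`, `ps_amplitude`.
#' @export
measure_sweeps <- function(sweeps) {
  do.call(rbind, lapply(sweeps, function(sw)
    data.frame(t_min = sw$t_min, fepsp_slope = fepsp_slope(sw),
               ps_amplitude = ps_amplitude(sw))))
}

#' Baseline-normalized LTP time course
#'
#' Each time point is the mean of its (nominally five) sweep measures; both
#' series are then expressed as a percentage of the mean of the first
#' `n_baseline` (pre-HFS) time points, so the baseline averages 100% by
#' construction. Time points with fewer than `min_sweeps` sweeps are
#' dropped with a message.
#'
#' @param measures Data frame as from [measure_sweeps()]: columns `t_min`
#'   (minutes relative to HFS, negative = baseline), `fepsp_slope`,
#'   `ps_amplitude`; several rows (sweeps) per time point.
#' @param n_baseline Number of baseline time points (default 6).
#' @param min_sweeps Minimum sweeps per time point (default 1).
#' @return Object of class `ltp_timecourse`: data frame `points` with
#'   columns `t_min`, `fepsp_pct`, `ps_pct`, `n_sweeps`.
#' @export
ltp_timecourse <- function(measures, n_baseline = 6, min_sweeps = 1) {
  stopifnot(all(c("t_min", "fepsp_slope", "ps_amplitude") %in% names(measures)))
  agg <- stats::aggregate(cbind(fepsp_slope, ps_amplitude) ~ t_min,
                          data = measures, FUN = mean)
  counts <- stats::aggregate(fepsp_slope ~ t_min, data = measures,
                             FUN = length)
  agg$n_sweeps <- counts$fepsp_slope[match(agg$t_min, counts$t_min)]
  drop <- agg$n_sweeps < min_sweeps
  if (any(drop)) {
    message("dropping time point(s) with too few sweeps: ",
            paste(agg$t_min[drop], collapse = ", "), " min")
    agg <- agg[!drop, , drop = FALSE]
  }
  agg <- agg[order(agg$t_min), , drop = FALSE]
  if (nrow(agg) < n_baseline)
    stop(sprintf("need at least %d baseline time points", n_baseline))
  base_idx <- seq_len(n_baseline)
  if (any(agg$t_min[base_idx] >= 0))
    stop(sprintf("the first %d time points must precede HFS (t_min < 0)",
                 n_baseline))
  fe_base <- mean(agg$fepsp_slope[base_idx])
  ps_base <- mean(agg$ps_amplitude[base_idx])
  if (fe_base <= 0 || ps_base <= 0) stop("non-positive baseline measure")
  structure(list(points = data.frame(
    t_min = agg$t_min,
    fepsp_pct = 100 * agg$fepsp_slope / fe_base,
    ps_pct = 100 * agg$ps_amplitude / ps_base,
    n_sweeps = agg$n_sweeps)),
    class = "ltp_timecourse")
}

#' @export
print.ltp_timecourse <- function(x, ...) {
  p <- x$points
  post <- p[p$t_min > 0, ]
  cat(sprintf("<ltp_timecourse> %d points; peak fEPSP %.1f%%, final fEPSP %.1f%%\n",
              nrow(p), max(post$fepsp_pct),
              p$fepsp_pct[which.max(p$t_min)]))
  invisible(x)
}

#' Generate, measure and normalize a full synthetic LTP experiment
#'
#' @param model A [plasticity_model()].
#' @param schedule Time points in minutes relative to HFS (default
#'   [ltp_schedule()]).
#' @param sweeps_per_point Sweeps averaged per point (default 5).
#' @param seed Integer seed.
#' @return An `ltp_timecourse`.
#' @export
gen_ltp_timecourse <- function(model, schedule = ltp_schedule(),
                               sweeps_per_point = 5, seed = 1) {
  set.seed(seed)
  rows <- lapply(schedule, function(tm) {
    sweeps <- lapply(seq_len(sweeps_per_point), function(i)
      gen_evoked_sweep(model, t_min = tm))
    measure_sweeps(sweeps)
  })
  ltp_timecourse(do.call(rbind, rows))
}

#' Recover plasticity parameters from an LTP time course
#'
#' Least-squares fit of `pct(t) = 100 * (1 + (pf - 1) * exp(-t / tau))` to
#' the post-HFS fEPSP percentages (via [minpack.lm::nlsLM()]).
#'
#' @param timecourse An `ltp_timecourse`.
#' @param series `"fepsp"` or `"ps"`.
#' @return List with `potentiation_factor` and `decay_tau_min`.
#' @export
fit_ltp_decay <- function(timecourse, series = c("fepsp", "ps")) {
  stopifnot(inherits(timecourse, "ltp_timecourse"))
  series <- match.arg(series)
  p <- timecourse$points
  post <- p[p$t_min > 0, ]
  y <- if (series == "fepsp") post$fepsp_pct else post$ps_pct
  t <- post$t_min
  start <- list(A = max(0.05, (max(y) - 100) / 100), tau = 120)
  fit <- minpack.lm::nlsLM(y ~ 100 * (1 + A * exp(-t / tau)),
                           start = start,
                           lower = c(A = 0, tau = 1),
                           upper = c(A = 10, tau = 1e6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(potentiation_factor = 1 + unname(co["A"]),
       decay_tau_min = unname(co["tau"]))
}
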