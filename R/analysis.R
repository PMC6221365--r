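#' Extract spike times from a recording log
#'
#' If the log carries a `spike` flag column it is authoritative. For flagless
#' logs (e.g. a bare voltage recording), spikes are detected as upward
#' crossings of a 0 mV threshold, with crossings closer than a 2 ms
#' refractory window merged into one event.
#'
#' @param log A [recording_log].
#' @param threshold Fallback detection threshold (mV).
#' @param refractory Merge window for threshold crossings (ms).
#' @return Strictly increasing spike times (ms); may be empty.
#' @export
detect_spikes <- function(log, threshold = 0, refractory = 2) {
  stopifnot(inherits(log, "recording_log"))
  if ("spike" %in% names(log)) return(log$t[log$spike > 0])
  v <- log$v
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  times <- log$t[up]
  keep <- c(TRUE, diff(times) > refractory)
  times[keep]
}

#' Align a recording to repeated stimulus onsets
#'
#' Cuts the log into trials of `window` ms starting at each onset, returning
#' the voltage trial matrix, per-trial spike rasters (times relative to
#' onset) and the trial-average voltage. Onsets whose window does not fit
#' inside the recording are dropped and counted.
#'
#' @param log A [recording_log].
#' @param onsets Stimulus onset times (ms); at least one.
#' @param window Trial window length (ms).
#' @return A list of class `aligned_trials`: `time` (ms relative to onset),
#'   `v` (trials x samples matrix), `rasters` (list of spike-time vectors),
#'   `v_mean`, `n_trials`, `n_dropped`.
#' @export
align_to_stimulus <- function(log, onsets, window) {
  stopifnot(inherits(log, "recording_log"))
  if (length(onsets) < 1) stop_invalid("need at least one onset")
  check_scalar(window, "window", positive = TRUE)
  dt <- attr(log, "dt")
  n_win <- as.integer(round(window / dt))
  t0 <- log$t[1]
  start_idx <- round((onsets - t0) / dt) + 1L
  ok <- start_idx >= 1L & (start_idx + n_win - 1L) <= nrow(log)
  n_dropped <- sum(!ok)
  if (!any(ok)) stop_invalid("no onset leaves a full window inside the log")
  start_idx <- start_idx[ok]
  kept_onsets <- onsets[ok]
  v <- t(vapply(start_idx, function(i) log$v[i:(i + n_win - 1L)],
                numeric(n_win)))
  spikes <- detect_spikes(log)
  rasters <- lapply(kept_onsets, function(on)
    spikes[spikes >= on & spikes < on + window] - on)
  structure(list(time = (seq_len(n_win) - 1) * dt, v = v, rasters = rasters,
                 v_mean = colMeans(v), n_trials = length(start_idx),
                 n_dropped = n_dropped, onsets = kept_onsets),
            class = "aligned_trials")
}

#' @export
print.aligned_trials <- function(x, ...) {
  cat(sprintf("<aligned_trials> %d trials x %d samples (%d dropped)\n",
              x$n_trials, length(x$time), x$n_dropped))
  invisible(x)
}

# Per-trial response metrics from a raster (spike times relative to onset).
trial_metrics <- function(raster) {
  n <- length(raster)
  c(count = n,
    latency = if (n >= 1) raster[1] else NA_real_,
    inst_rate = if (n >= 2) 1000 / (raster[2] - raster[1]) else NA_real_)
}

#' Amplitude tuning curves over an input-gain sweep
#'
#' Re-runs a stimulus protocol at each swept gain value and summarises the
#' aligned rasters: mean spike count per stimulus, instantaneous rate
#' (1/first interspike interval, Hz), mean first-spike latency (ms) and
#' first-spike jitter (SD of latency across trials, ms). Sweep points where
#' no trial spikes get a zero count and `NA` (flagged undefined) latency.
#'
#' @param protocol A list with fields `gains` (>= 3 swept values), `onsets`
#'   (>= 5 stimulus onset times, ms) and `window` (ms).
#' @param simulator A function `(gain) -> recording_log` running the
#'   experiment at one gain.
#' @return A `data.frame` of class `tuning_curve`: one row per gain with
#'   columns `gain`, `n_trials`, `mean_count`, `inst_rate`, `latency`,
#'   `jitter`.
#' @export
tuning_curves <- function(protocol, simulator) {
  stopifnot(is.list(protocol), is.function(simulator))
  gains <- protocol$gains
  if (length(gains) < 3) stop_invalid("need at least 3 swept gain values")
  if (length(protocol$onsets) < 5)
    stop_invalid("need at least 5 stimulus repeats per gain")
  rows <- lapply(gains, function(g) {
    log <- simulator(g)
    al <- align_to_stimulus(log, protocol$onsets, protocol$window)
    m <- t(vapply(al$rasters, trial_metrics, numeric(3)))
    lat <- m[, "latency"]
    data.frame(gain = g, n_trials = al$n_trials,
               mean_count = mean(m[, "count"]),
               inst_rate = if (all(is.na(m[, "inst_rate"]))) NA_real_
                           else mean(m[, "inst_rate"], na.rm = TRUE),
               latency = if (all(is.na(lat))) NA_real_
                         else mean(lat, na.rm = TRUE),
               jitter = if (sum(!is.na(lat)) >= 2) sd(lat[!is.na(lat)])
                        else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tuning_curve", "data.frame")
  out
}

#' Vector strength of phase locking
#'
#' Projects each spike onto its phase within the stimulus period (phase 0 at
#' the rising edge) and returns the length of the mean resultant vector:
#' `VS = |sum(exp(i theta_k))| / N`. 1 means perfect locking, values near 0
#' a uniform phase distribution.
#'
#' @param spike_times Spike times (ms); at least one.
#' @param period Stimulus period (ms).
#' @return A list of class `vector_strength`: `vs`, `mean_phase` (radians in
#'   `[0, 2 pi)`), `n`.
#' @export
vector_strength <- function(spike_times, period) {
  check_scalar(period, "period", positive = TRUE)
  if (length(spike_times) < 1)
    stop_invalid("vector strength is undefined for zero spikes")
  theta <- 2 * pi * ((spike_times %% period) / period)
  cs <- sum(cos(theta)); sn <- sum(sin(theta))
  structure(list(vs = sqrt(cs^2 + sn^2) / length(theta),
                 mean_phase = atan2(sn, cs) %% (2 * pi),
                 n = length(theta)),
            class = "vector_strength")
}

#' @export
print.vector_strength <- function(x, ...) {
  cat(sprintf("<vector_strength> VS=%.3f mean phase=%.2f rad (n=%d)\n",
              x$vs, x$mean_phase, x$n))
  invisible(x)
}

#' Null distribution quantile for vector strength
#'
#' Phase-shuffled surrogate: the vector strength of `n` spikes with phases
#' drawn uniformly, resampled `n_resamples` times. Used as the significance
#' threshold for observed phase locking.
#'
#' @param n Number of spikes in the observed train.
#' @param q Quantile of the null (default 0.95).
#' @param n_resamples Number of surrogates (default 1000).
#' @param seed RNG seed for the surrogate draw.
#' @return The `q` quantile of the surrogate VS distribution.
#' @export
vs_null_quantile <- function(n, q = 0.95, n_resamples = 1000, seed = 1) {
  if (n < 1) stop_invalid("need at least one spike")
  null_vs <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    theta <- runif(n, 0, 2 * pi)
    sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / n
  }, numeric(1)))
  unname(quantile(null_vs, q))
}

#' Stochastic-resonance noise sweep
#'
#' Runs a subthreshold periodic protocol at increasing membrane-noise
#' amplitudes and measures, per amplitude, the mean spike count and mean
#' vector strength across seeds. The drive must be verified subthreshold:
#' the zero-noise run has to produce no spikes, otherwise a precondition
#' error is raised. The sweep reports the amplitude maximising VS; in a
#' stochastic-resonance regime this is an intermediate noise level.
#'
#' @param amplitudes Noise SDs, sorted ascending and starting at 0.
#' @param protocol A list with `params` (a [mode_params()]), `drive` (the
#'   per-sample subthreshold current trace), `period` (stimulus period, ms)
#'   and optionally `dt` (default 1 ms).
#' @param n_seeds Seeds per amplitude (default 20).
#' @param seed Base seed; run `s` of amplitude `k` uses `seed + s` combined
#'   with `k`.
#' @return A `data.frame` of class `sr_sweep`: `amplitude`, `mean_count`,
#'   `mean_vs` (over seeds with at least one spike), `n_active_seeds`; the
#'   VS-maximising amplitude is in `attr(, "best_amplitude")`.
#' @export
stochastic_resonance_sweep <- function(amplitudes, protocol, n_seeds = 20,
                                       seed = 1) {
  if (length(amplitudes) < 2 || amplitudes[1] != 0 ||
      is.unsorted(amplitudes, strictly = TRUE))
    stop_invalid("`amplitudes` must be strictly ascending and start at 0")
  stopifnot(is.list(protocol), inherits(protocol$params, "mode_params"))
  dt <- if (is.null(protocol$dt)) 1 else protocol$dt
  drive <- as.numeric(protocol$drive)
  period <- protocol$period
  check_scalar(period, "period", positive = TRUE)

  base <- simulate_unit(protocol$params, drive, dt = dt)
  if (length(base$spike_times) > 0)
    stop_invalid("protocol is not subthreshold: %d spike(s) at zero noise",
                 length(base$spike_times))

  duration <- length(drive) * dt
  rows <- lapply(seq_along(amplitudes), function(k) {
    amp <- amplitudes[k]
    counts <- numeric(n_seeds)
    vss <- rep(NA_real_, n_seeds)
    for (s in seq_len(n_seeds)) {
      if (amp == 0) {
        st <- base$spike_times
      } else {
        noise <- noise_current(amp, duration, dt,
                               seed = derive_seed(seed + s, sprintf("amp%d", k)))
        st <- simulate_unit(protocol$params, drive + noise, dt = dt)$spike_times
      }
      counts[s] <- length(st)
      if (length(st) > 0) vss[s] <- vector_strength(st, period)$vs
    }
    data.frame(amplitude = amp, mean_count = mean(counts),
               mean_vs = if (all(is.na(vss))) NA_real_
                         else mean(vss, na.rm = TRUE),
               n_active_seeds = sum(!is.na(vss)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sr_sweep", "data.frame")
  with_vs <- which(!is.na(out$mean_vs))
  attr(out, "best_amplitude") <-
    if (length(with_vs)) out$amplitude[with_vs[which.max(out$mean_vs[with_vs])]]
    else NA_real_
  out
}

new_linear_filter <- function(lag, values, n_spikes = NA_integer_,
                              n_excluded = 0L, uninformative = FALSE,
                              level = "spike") {
  structure(list(lag = lag, values = values, n_spikes = n_spikes,
                 n_excluded = n_excluded, uninformative = uninformative,
                 level = level),
            class = "linear_filter")
}

#' @export
print.linear_filter <- function(x, ...) {
  cat(sprintf("<linear_filter> %s level: %d lags (0-%g ms before response)%s\n",
              x$level, length(x$lag), max(x$lag),
              if (x$uninformative) "  [uninformative stimulus]" else ""))
  if (!is.na(x$n_spikes))
    cat(sprintf("  n_spikes=%d (%d excluded before first full window)\n",
                x$n_spikes, x$n_excluded))
  invisible(x)
}

#' Spike-triggered average (reverse correlation at the spike level)
#'
#' Averages the stimulus segments preceding each spike on the stimulus frame
#' grid: the linear filter, or time-reversed impulse response, of the cell.
#' Lags run most-recent-first (lag 0 = the frame containing the spike).
#' Spikes earlier than one full window after stimulus onset are excluded and
#' counted.
#'
#' @param frame_values Stimulus value per frame.
#' @param frame_times Frame onset times (ms), uniformly spaced.
#' @param spike_times Spike times (ms).
#' @param window Filter window length (ms).
#' @return A `linear_filter` with `lag` (ms before the spike, ascending) and
#'   `values` in stimulus units. A constant stimulus yields a constant,
#'   `uninformative`-flagged filter.
#' @export
sta <- function(frame_values, frame_times, spike_times, window) {
  check_scalar(window, "window", positive = TRUE)
  if (length(frame_values) != length(frame_times))
    stop_invalid("frame_values and frame_times must have equal length")
  if (length(frame_times) < 2) stop_invalid("need at least 2 frames")
  frame_ms <- frame_times[2] - frame_times[1]
  n_lags <- as.integer(ceiling(window / frame_ms))
  spike_frame <- findInterval(spike_times, frame_times)
  usable <- spike_frame >= n_lags
  n_excluded <- sum(!usable)
  spike_frame <- spike_frame[usable]
  if (length(spike_frame) == 0)
    stop_invalid("no usable spikes after the first full window")
  segs <- vapply(spike_frame, function(f)
    frame_values[f:(f - n_lags + 1L)], numeric(n_lags))
  values <- rowMeans(segs)
  new_linear_filter(lag = (seq_len(n_lags) - 1) * frame_ms, values = values,
                    n_spikes = length(spike_frame), n_excluded = n_excluded,
                    uninformative = stats::var(frame_values) == 0,
                    level = "spike")
}

#' Subthreshold linear filter (response-weighted average)
#'
#' Cross-correlates the mean-subtracted membrane potential with a zero-mean
#' stimulus over the window and normalises by the stimulus variance, so that
#' an identity system (`v` equal to the stimulus delayed by `k` samples)
#' yields a unit impulse at lag `k`.
#'
#' @param stimulus Zero-mean stimulus trace (one value per sample).
#' @param v Membrane potential trace, aligned with `stimulus`.
#' @param window Filter window length (ms).
#' @param dt Sampling step (ms).
#' @return A `linear_filter` (`level = "subthreshold"`) with `lag` in ms
#'   before the response, ascending.
#' @export
subthreshold_filter <- function(stimulus, v, window, dt = 1) {
  check_scalar(window, "window", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  if (length(stimulus) != length(v))
    stop_invalid("stimulus and v must be aligned (equal length)")
  if (stats::var(stimulus) == 0)
    stop_invalid("zero-variance stimulus: filter undefined")
  if (abs(mean(stimulus)) > 0.05 * sd(stimulus))
    stop_invalid("stimulus must be (near) zero-mean; centre it first")
  n <- length(stimulus)
  n_lags <- as.integer(round(window / dt)) + 1L
  vc <- v - mean(v)
  denom <- sum(stimulus^2)
  values <- vapply(seq_len(n_lags) - 1L, function(k)
    sum(vc[(k + 1):n] * stimulus[1:(n - k)]) / denom, numeric(1))
  new_linear_filter(lag = (seq_len(n_lags) - 1L) * dt, values = values,
                    level = "subthreshold")
}

#' Count significant sign changes of a linear filter
#'
#' Classifies filter shape (monophasic, biphasic, ...) robustly: lags whose
#' magnitude is below `lobe_frac` of the peak magnitude are ignored, and the
#' sign changes of the remaining lobes are counted. 0 = monophasic,
#' 1 = biphasic, 2 = triphasic.
#'
#' @param filter A `linear_filter` (or bare numeric vector).
#' @param lobe_frac Fraction of the peak magnitude a lobe must reach to
#'   count (default 0.3).
#' @return Integer number of sign changes.
#' @export
filter_sign_changes <- function(filter, lobe_frac = 0.3) {
  f <- if (inherits(filter, "linear_filter")) filter$values else as.numeric(filter)
  peak <- max(abs(f))
  if (peak == 0) return(0L)
  f[abs(f) < lobe_frac * peak] <- 0
  sg <- sign(f)
  sg <- sg[sg != 0]
  if (length(sg) < 2) return(0L)
  sum(diff(sg) != 0)
}
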