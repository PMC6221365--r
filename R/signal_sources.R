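#' Stimulus generator settings
#'
#' Configuration of the on-board stimulus generator (port 1), which can emit
#' periodic square pulses, frame-wise binary noise, or play back an external
#' trace.
#'
#' @param kind One of `"square"`, `"binary_noise"`, `"external"`.
#' @param rate Square-pulse repetition rate (Hz, dial 1); `0` gives an
#'   all-low trace.
#' @param duty Fraction of each period spent high (default 0.5, i.e. a 50%
#'   duty cycle).
#' @param noise_frame_rate Binary-noise frame rate (Hz); the stimulus holds
#'   each drawn level for one frame (default 50 Hz).
#' @param amplitude High level of the stimulus (model current or light
#'   units).
#' @param seed Integer seed making binary noise reproducible; required for
#'   `kind = "binary_noise"`.
#' @param trace Numeric vector played back verbatim when `kind = "external"`
#'   (one value per `dt` sample).
#'
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(kind = c("square", "binary_noise", "external"),
                            rate = 1, duty = 0.5, noise_frame_rate = 50,
                            amplitude = 1, seed = NULL, trace = NULL) {
  kind <- match.arg(kind)
  check_scalar(rate, "rate")
  check_scalar(duty, "duty")
  check_scalar(noise_frame_rate, "noise_frame_rate", positive = TRUE)
  check_scalar(amplitude, "amplitude")
  if (rate < 0) stop_invalid("`rate` must be >= 0")
  if (duty < 0 || duty > 1) stop_invalid("`duty` must lie in [0, 1]")
  if (kind == "binary_noise" && is.null(seed))
    stop_invalid("binary-noise stimulus needs a `seed` for reproducibility")
  if (kind == "external" && is.null(trace))
    stop_invalid("external stimulus needs a `trace`")
  structure(list(kind = kind, rate = rate, duty = duty,
                 noise_frame_rate = noise_frame_rate, amplitude = amplitude,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 trace = trace),
            class = "stimulus_config")
}

#' Front-panel dial settings
#'
#' The four rotary dials of the device: stimulus rate (dial 1, when port 1 is
#' in generator mode), the shared analog-in / synapse-2 gain (dial 2),
#' membrane noise amplitude (dial 3) and static input current (dial 4).
#' Dial 1 doubles as the synapse-1 gain when port 1 is used as a synapse.
#'
#' @param stim_rate Stimulus repetition rate (Hz).
#' @param input_gain Signed gain applied to the analog-in trace (and to
#'   synapse 2 for externally supplied spike trains).
#' @param noise_amplitude Standard deviation of the membrane noise current
#'   (model units); must be non-negative.
#' @param static_current Constant holding current (model units).
#' @param synapse1_gain Signed gain of synapse port 1.
#'
#' @return An object of class `dial_settings`.
#' @export
dial_settings <- function(stim_rate = 1, input_gain = 1, noise_amplitude = 0,
                          static_current = 0, synapse1_gain = 1) {
  check_scalar(stim_rate, "stim_rate")
  check_scalar(input_gain, "input_gain")
  check_scalar(noise_amplitude, "noise_amplitude")
  check_scalar(static_current, "static_current")
  check_scalar(synapse1_gain, "synapse1_gain")
  if (noise_amplitude < 0) stop_invalid("`noise_amplitude` must be >= 0")
  structure(list(stim_rate = stim_rate, input_gain = input_gain,
                 noise_amplitude = noise_amplitude,
                 static_current = static_current,
                 synapse1_gain = synapse1_gain),
            class = "dial_settings")
}

#' Periodic square-pulse stimulus
#'
#' Generates the default output of the stimulus port: pulses at `config$rate`
#' Hz with the high phase starting each period (rising edge at t = 0) and
#' lasting `duty` of the period.
#'
#' @param config A [stimulus_config()] with `kind = "square"`.
#' @param duration Trace duration (ms).
#' @param dt Sampling step (ms).
#' @return Numeric vector taking values `0` and `config$amplitude`.
#' @export
square_stimulus <- function(config, duration, dt = 1) {
  stopifnot(inherits(config, "stimulus_config"))
  if (config$kind != "square")
    stop_invalid("square_stimulus() needs kind = \"square\" (got %s)", config$kind)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  n <- round(duration / dt)
  if (n < 1 || n > 5e8)
    stop_invalid("duration/dt gives %g samples; not representable", n)
  t <- (seq_len(n) - 1) * dt
  if (config$rate == 0) return(rep(0, n))
  period <- 1000 / config$rate
  ifelse((t %% period) < config$duty * period, config$amplitude, 0)
}

#' Frame-wise binary noise stimulus
#'
#' Draws one of two levels independently and equiprobably per frame of
#' `1000 / noise_frame_rate` ms and holds it for the frame, mirroring the
#' stimulus port's binary-noise flag. By default the levels are symmetric
#' (`-amplitude`, `+amplitude`); `light = TRUE` shifts them to
#' (`0`, `amplitude`) for driving the photoreceptor, since light is
#' non-negative.
#'
#' @param config A [stimulus_config()] with `kind = "binary_noise"` and a
#'   `seed`.
#' @param duration Trace duration (ms).
#' @param dt Sampling step (ms).
#' @param light Use light levels `{0, amplitude}` instead of symmetric ones.
#' @return A list of class `binary_noise` with `trace` (per-sample values),
#'   `frame_times` (onset of each frame, ms), `frame_values` (one value per
#'   frame) and `frame_ms`.
#' @export
binary_noise_stimulus <- function(config, duration, dt = 1, light = FALSE) {
  stopifnot(inherits(config, "stimulus_config"))
  if (config$kind != "binary_noise")
    stop_invalid("binary_noise_stimulus() needs kind = \"binary_noise\"")
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  frame_ms <- 1000 / config$noise_frame_rate
  if (frame_ms < dt)
    stop_invalid("noise frame (%g ms) shorter than dt (%g ms)", frame_ms, dt)
  n <- round(duration / dt)
  n_frames <- as.integer(ceiling(duration / frame_ms))
  levels <- if (light) c(0, config$amplitude)
            else c(-config$amplitude, config$amplitude)
  frame_values <- with_seed(config$seed,
                            sample(levels, n_frames, replace = TRUE))
  t <- (seq_len(n) - 1) * dt
  idx <- pmin(floor(t / frame_ms) + 1L, n_frames)
  structure(list(trace = frame_values[idx],
                 frame_times = (seq_len(n_frames) - 1) * frame_ms,
                 frame_values = frame_values,
                 frame_ms = frame_ms),
            class = "binary_noise")
}

#' Photoreceptor transduction current
#'
#' First-order adapting transduction: an adaptation state `A` relaxes toward
#' the light level `L` with time constant `photo_adaptation_tau`, and the
#' transduced current is
#' `photo_polarity * photo_gain * (L - A) + photo_baseline`. Short time
#' constants give transient (high-pass) responses, long ones near-sustained
#' responses; the baseline sets the dark current. `A` starts adapted to the
#' initial light level.
#'
#' @param light_trace Non-negative light levels, one per sample.
#' @param params A [mode_params()] supplying polarity, tau, gain, baseline.
#' @param dt Sampling step (ms).
#' @return Numeric current trace (model units), same length as the input.
#' @export
photo_current <- function(light_trace, params, dt = 1) {
  stopifnot(inherits(params, "mode_params"))
  check_scalar(dt, "dt", positive = TRUE)
  if (length(light_trace) == 0) stop_invalid("`light_trace` must be non-empty")
  if (any(!is.finite(light_trace)) || any(light_trace < 0))
    stop_invalid("`light_trace` must be finite and non-negative")
  photo_current_cpp(as.numeric(light_trace), params$photo_polarity,
                    params$photo_gain, params$photo_adaptation_tau,
                    params$photo_baseline, dt)
}

#' Exponential synapse current from a presynaptic spike train
#'
#' Each presynaptic event adds an instantaneous jump of `gain` to the
#' synaptic current, which then decays exponentially with `tau_syn`;
#' contributions from successive events sum linearly. Negative gains yield
#' hyperpolarising (inhibitory) current.
#'
#' @param presyn_spike_times Event times (ms) within `[0, duration)`.
#' @param gain Signed jump per event (model units).
#' @param tau_syn Decay time constant (ms); must be positive.
#' @param duration Trace duration (ms).
#' @param dt Sampling step (ms).
#' @return Numeric current trace of `round(duration/dt)` samples.
#' @export
synapse_current <- function(presyn_spike_times, gain, tau_syn = 10,
                            duration, dt = 1) {
  check_scalar(gain, "gain")
  check_scalar(tau_syn, "tau_syn", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  n <- as.integer(round(duration / dt))
  if (length(presyn_spike_times) == 0) return(rep(0, n))
  if (any(!is.finite(presyn_spike_times)) ||
      any(presyn_spike_times < 0 | presyn_spike_times >= duration))
    stop_invalid("spike times must lie in [0, duration)")
  idx <- sort(as.integer(floor(presyn_spike_times / dt)))
  synapse_current_cpp(idx, gain, tau_syn, n, dt)
}

#' Membrane noise current
#'
#' Zero-mean Gaussian current, independent across samples, with standard
#' deviation `amplitude` (dial 3). Reproducible from `seed`.
#'
#' @param amplitude Noise SD (model units); must be non-negative.
#' @param duration Trace duration (ms).
#' @param dt Sampling step (ms).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Numeric current trace.
#' @export
noise_current <- function(amplitude, duration, dt = 1, seed = NULL) {
  check_scalar(amplitude, "amplitude")
  if (amplitude < 0) stop_invalid("`amplitude` must be >= 0")
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  n <- as.integer(round(duration / dt))
  if (amplitude == 0) return(rep(0, n))
  with_seed(seed, rnorm(n, mean = 0, sd = amplitude))
}

#' Sum per-channel currents into the total model drive
#'
#' Collects the per-channel current traces and their elementwise sum
#' `i_total`, the quantity driving the neuron. Channels left `NULL` are
#' treated as silent (all-zero).
#'
#' @param i_photo,i_syn1,i_syn2,i_analog,i_noise,i_static Equal-length
#'   per-channel current traces (any may be `NULL`).
#' @return A `data.frame` of class `current_breakdown` with one column per
#'   channel plus `i_total`.
#' @export
sum_currents <- function(i_photo = NULL, i_syn1 = NULL, i_syn2 = NULL,
                         i_analog = NULL, i_noise = NULL, i_static = NULL) {
  chans <- list(i_photo = i_photo, i_syn1 = i_syn1, i_syn2 = i_syn2,
                i_analog = i_analog, i_noise = i_noise, i_static = i_static)
  lens <- unique(vapply(Filter(Negate(is.null), chans), length, integer(1)))
  if (length(lens) == 0) stop_invalid("at least one channel must be supplied")
  if (length(lens) > 1)
    stop_invalid("channel traces have mismatching lengths (%s)",
                 paste(lens, collapse = ", "))
  n <- lens
  chans <- lapply(chans, function(x) if (is.null(x)) rep(0, n) else as.numeric(x))
  out <- as.data.frame(chans)
  out$i_total <- rowSums(out)
  class(out) <- c("current_breakdown", "data.frame")
  out
}
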