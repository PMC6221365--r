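#' Neuron preset parameters
#'
#' Bundles the four Izhikevich coefficients with the photoreceptor channel
#' settings that together define one selectable "mode" of the simulated
#' neuron. Currents are in the dimensionless model units of the mV-scaled
#' Izhikevich equations; no physical pA mapping is claimed.
#'
#' @param label Short name for the preset.
#' @param a Recovery time scale (1/ms); must be positive.
#' @param b Recovery sensitivity (dimensionless).
#' @param c Post-spike reset potential (mV); must lie below the 30 mV cutoff.
#' @param d Post-spike recovery increment (model units).
#' @param photo_polarity `+1` for an ON (light-depolarised) photoreceptor,
#'   `-1` for OFF.
#' @param photo_adaptation_tau Photoreceptor adaptation time constant (ms);
#'   small values give transient (high-pass) light responses, large values
#'   near-sustained ones.
#' @param photo_baseline Constant current added in darkness (model units);
#'   positive values give a basal spike rate without any input.
#' @param photo_gain Scaling from light units to model current.
#' @param description Free-text summary of the expected firing phenotype.
#'
#' @return An object of class `mode_params`.
#' @seealso [preset_modes()] for the five shipped presets.
#' @export
mode_params <- function(label, a, b, c, d,
                        photo_polarity = 1,
                        photo_adaptation_tau = 500,
                        photo_baseline = 0,
                        photo_gain = 1,
                        description = "") {
  check_scalar(a, "a", positive = TRUE)
  check_scalar(b, "b")
  check_scalar(c, "c")
  check_scalar(d, "d")
  check_scalar(photo_adaptation_tau, "photo_adaptation_tau", positive = TRUE)
  check_scalar(photo_baseline, "photo_baseline")
  check_scalar(photo_gain, "photo_gain")
  if (c >= 30)
    stop_invalid("reset potential c must be below the 30 mV spike cutoff")
  if (!photo_polarity %in% c(-1, 1))
    stop_invalid("photo_polarity must be +1 (ON) or -1 (OFF)")
  structure(
    list(label = as.character(label), a = a, b = b, c = c, d = d,
         photo_polarity = photo_polarity,
         photo_adaptation_tau = photo_adaptation_tau,
         photo_baseline = photo_baseline,
         photo_gain = photo_gain,
         description = as.character(description)),
    class = "mode_params")
}

#' @export
print.mode_params <- function(x, ...) {
  cat(sprintf("<mode_params> %s\n", x$label))
  cat(sprintf("  a=%g b=%g c=%g d=%g\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  photoreceptor: polarity %+d, tau %g ms, baseline %g, gain %g\n",
              x$photo_polarity, x$photo_adaptation_tau, x$photo_baseline,
              x$photo_gain))
  if (nzchar(x$description)) cat(sprintf("  %s\n", x$description))
  invisible(x)
}

#' The five shipped neuron modes
#'
#' Returns the preset table toggled by the device's mode button. The firing
#' phenotypes follow the canonical published Izhikevich parameter sets
#' (regular spiking, fast spiking, bursting, low-threshold spiking), paired
#' with photoreceptor settings that produce the described light responses:
#'
#' 1. Slowly adapting ON unit (regular spiking; slow photo adaptation).
#' 2. Transient OFF unit with a rebound burst at light offset (intrinsic
#'    burster; fast photo adaptation). Two such units wired to mutually
#'    excite each other form a basic central pattern generator.
#' 3. Sustained OFF unit with an elevated basal rate in darkness
#'    (regular spiking; near-tonic photoreceptor plus dark baseline current).
#' 4. Fast-spiking ON unit with fast photo adaptation.
#' 5. Low-threshold spiking ON unit with slow photo adaptation.
#'
#' @return A list of exactly five [mode_params()] objects, in button order.
#' @export
preset_modes <- function() {
  list(
    mode_params("ON slow (regular spiking)",
                a = 0.02, b = 0.2, c = -65, d = 8,
                photo_polarity = 1, photo_adaptation_tau = 500,
                description = "Slowly adapting light-ON neuron: a light step elicits a burst that gradually slows."),
    mode_params("OFF transient (bursting)",
                a = 0.02, b = 0.25, c = -50, d = 6,
                photo_polarity = -1, photo_adaptation_tau = 50,
                description = "Transient light-OFF neuron: rapidly adapting rebound burst when the light is removed."),
    mode_params("OFF sustained (dark-active)",
                a = 0.02, b = 0.2, c = -65, d = 8,
                photo_polarity = -1, photo_adaptation_tau = 10000,
                photo_baseline = 6,
                description = "Sustained light-OFF neuron with an elevated basal spike rate in darkness."),
    mode_params("ON fast (fast spiking)",
                a = 0.1, b = 0.2, c = -65, d = 2,
                photo_polarity = 1, photo_adaptation_tau = 50,
                description = "Fast-spiking light-ON neuron with transient photo responses."),
    mode_params("ON slow (low-threshold spiking)",
                a = 0.02, b = 0.25, c = -65, d = 2,
                photo_polarity = 1, photo_adaptation_tau = 500,
                description = "Low-threshold spiking light-ON neuron; fires readily at weak drive.")
  )
}

#' Instantaneous neuron state
#'
#' @param v Membrane potential (mV).
#' @param u Recovery variable (model units).
#' @param spiked Whether the reset fired on the step just completed.
#' @param t Elapsed model time (ms).
#'
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(v, u, spiked = FALSE, t = 0) {
  check_scalar(v, "v")
  check_scalar(u, "u")
  check_scalar(t, "t")
  structure(list(v = v, u = u, spiked = isTRUE(spiked), t = t),
            class = "neuron_state")
}

#' @export
print.neuron_state <- function(x, ...) {
  cat(sprintf("<neuron_state> t=%g ms  v=%.3f mV  u=%.3f%s\n",
              x$t, x$v, x$u, if (x$spiked) "  [spiked]" else ""))
  invisible(x)
}

#' Resting state of a preset under a constant holding current
#'
#' Solves for the stable fixed point of the subthreshold dynamics
#' (`0.04 v^2 + 5 v + 140 - u + I = 0` with `u = b v`). If the holding
#' current is suprathreshold (no fixed point exists), the state is started
#' from the reset potential instead.
#'
#' @param params A [mode_params()] object.
#' @param i_hold Constant holding current (model units).
#' @return A [neuron_state()] at the fixed point (or at reset).
#' @export
resting_state <- function(params, i_hold = 0) {
  stopifnot(inherits(params, "mode_params"))
  check_scalar(i_hold, "i_hold")
  disc <- (5 - params$b)^2 - 0.16 * (140 + i_hold)
  v <- if (disc >= 0) (-(5 - params$b) - sqrt(disc)) / 0.08 else params$c
  neuron_state(v = v, u = params$b * v)
}

#' Advance the neuron by one sampling step
#'
#' Integrates the Izhikevich equations
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I` and `du/dt = a (b v - u)` by
#' forward Euler with two half-steps for `v` per full step of `u`, applied on
#' an internal substep grid (`n_sub` substeps per sampling step) so that the
#' integration error is independent of the logging rate. A state whose
#' membrane potential has reached the 30 mV cutoff is reset (`v <- c`,
#' `u <- u + d`) and flagged as a spike; after integration `v` is clamped at
#' the cutoff, so a step reaching exactly 30 mV counts as a spike and no
#' returned sample exceeds 30 mV.
#'
#' @param state A [neuron_state()].
#' @param params A [mode_params()].
#' @param i_total Total input current over the step (model units).
#' @param dt Sampling step (ms); must be positive.
#' @param n_sub Number of integration substeps per sampling step; defaults to
#'   a 10-microsecond substep.
#' @return The advanced [neuron_state()]; `$spiked` is `TRUE` iff the reset
#'   fired during the step.
#' @export
step_neuron <- function(state, params, i_total, dt = 1, n_sub = NULL) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "mode_params"))
  check_scalar(i_total, "i_total")
  check_scalar(dt, "dt", positive = TRUE)
  if (!is.finite(state$v) || !is.finite(state$u))
    stop_invalid("neuron state must be finite")
  if (is.null(n_sub)) n_sub <- default_n_sub(dt)
  # an entering state already at the cutoff resets exactly, without
  # integrating: v <- c, u <- u + d
  if (state$v >= 30) {
    return(neuron_state(v = params$c, u = state$u + params$d,
                        spiked = TRUE, t = state$t + dt))
  }
  out <- izh_simulate_cpp(state$v, state$u, params$a, params$b, params$c,
                          params$d, i_total, dt, as.integer(n_sub))
  neuron_state(v = out$v_end, u = out$u_end, spiked = out$spiked[1],
               t = state$t + dt)
}

#' Simulate one unit under a prescribed current trace
#'
#' Runs the neuron over an arbitrary total-current time series. The returned
#' traces are sampled once per `dt`, with sample `i` giving the state after
#' the step driven by `current_trace[i]`; timestamps start at 0 so they align
#' with the driving stimulus samples. Samples on which the reset fired are
#' logged at the 30 mV spike peak (the integrator itself continues from the
#' post-reset state), so flag-less voltage traces remain usable for
#' threshold-based spike detection.
#'
#' @param params A [mode_params()].
#' @param current_trace Numeric vector of total input current per sample
#'   (model units); must be non-empty and finite.
#' @param dt Sampling step (ms).
#' @param init Initial [neuron_state()]; defaults to the resting state under
#'   the first current sample (see [resting_state()]).
#' @param n_sub Integration substeps per sample (see [step_neuron()]).
#' @return A list of class `unit_sim` with elements `t`, `v`, `u`, `spiked`
#'   (per sample) and `spike_times` (ms, strictly increasing).
#' @export
simulate_unit <- function(params, current_trace, dt = 1, init = NULL,
                          n_sub = NULL) {
  stopifnot(inherits(params, "mode_params"))
  if (length(current_trace) == 0)
    stop_invalid("`current_trace` must be non-empty")
  if (!is.numeric(current_trace) || any(!is.finite(current_trace)))
    stop_invalid("`current_trace` must be finite numeric")
  check_scalar(dt, "dt", positive = TRUE)
  if (is.null(n_sub)) n_sub <- default_n_sub(dt)
  if (is.null(init)) init <- resting_state(params, i_hold = current_trace[1])
  stopifnot(inherits(init, "neuron_state"))
  out <- izh_simulate_cpp(init$v, init$u, params$a, params$b, params$c,
                          params$d, as.numeric(current_trace), dt,
                          as.integer(n_sub))
  t <- (seq_along(current_trace) - 1) * dt
  structure(list(t = t, v = out$v, u = out$u, spiked = out$spiked,
                 spike_times = t[out$spiked], dt = dt, params = params),
            class = "unit_sim")
}

#' @export
print.unit_sim <- function(x, ...) {
  cat(sprintf("<unit_sim> %s: %d samples at dt=%g ms, %d spikes\n",
              x$params$label, length(x$v), x$dt, length(x$spike_times)))
  invisible(x)
}
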