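#' Specification of one unit in a simulation
#'
#' Describes one simulated neuron: its mode (preset index or explicit
#' [mode_params()]), dial settings, and optional attached inputs — a light
#' trace on the photodiode, an external analog-in trace (port 3), and/or the
#' on-board stimulus generator on port 1. A generated stimulus is routed
#' either to the analog-in port (the port-1-to-port-3 cable) or to the
#' photodiode via an LED (`stimulus_route = "light"`).
#'
#' @param unit_id Unique identifier (string) within a simulation.
#' @param mode Preset index 1-5 (see [preset_modes()]) or a [mode_params()].
#' @param dials A [dial_settings()].
#' @param light Optional per-sample light trace (non-negative).
#' @param analog Optional per-sample analog-in trace; scaled by
#'   `dials$input_gain`.
#' @param stimulus Optional [stimulus_config()] occupying port 1 (which then
#'   cannot receive synaptic wiring).
#' @param stimulus_route `"analog"` (scaled by `dials$input_gain`) or
#'   `"light"` (added to the light trace).
#'
#' @return An object of class `unit_spec`.
#' @export
unit_spec <- function(unit_id, mode = 1, dials = dial_settings(),
                      light = NULL, analog = NULL, stimulus = NULL,
                      stimulus_route = c("analog", "light")) {
  stimulus_route <- match.arg(stimulus_route)
  if (!is.character(unit_id) || length(unit_id) != 1L || !nzchar(unit_id))
    stop_invalid("`unit_id` must be a non-empty string")
  if (is.numeric(mode)) {
    presets <- preset_modes()
    if (length(mode) != 1L || !mode %in% seq_along(presets))
      stop_invalid("mode index must be in 1..%d", length(presets))
    mode <- presets[[mode]]
  }
  stopifnot(inherits(mode, "mode_params"), inherits(dials, "dial_settings"))
  if (!is.null(stimulus)) stopifnot(inherits(stimulus, "stimulus_config"))
  if (!is.null(light) && (any(!is.finite(light)) || any(light < 0)))
    stop_invalid("light trace must be finite and non-negative")
  structure(list(unit_id = unit_id, mode = mode, dials = dials,
                 light = light, analog = analog, stimulus = stimulus,
                 stimulus_route = stimulus_route),
            class = "unit_spec")
}

#' Directed wiring between units
#'
#' Edges connect a source unit's digital spike output (port 4) to a synapse
#' port (1 or 2) of a target unit, with a signed synaptic gain. Self-loops
#' are permitted; wiring into a synapse port occupied by the stimulus
#' generator is a configuration error (checked at run time).
#'
#' @param src,dst Character vectors of unit ids (recycled to equal length).
#' @param port Target synapse port, `1` or `2`.
#' @param gain Signed synaptic gain (jump per presynaptic spike).
#'
#' @return A `data.frame` of class `wiring_graph`.
#' @export
wiring_graph <- function(src = character(), dst = character(), port = integer(),
                         gain = numeric()) {
  edges <- data.frame(src = as.character(src), dst = as.character(dst),
                      port = as.integer(port), gain = as.numeric(gain),
                      stringsAsFactors = FALSE)
  if (nrow(edges) && !all(edges$port %in% c(1L, 2L)))
    stop_invalid("synapse port must be 1 or 2")
  class(edges) <- c("wiring_graph", "data.frame")
  edges
}

# Resolve one unit's non-synaptic drive into per-channel traces.
resolve_unit_inputs <- function(unit, n, dt, master_seed) {
  duration <- n * dt
  fit <- function(x, what) {
    if (is.null(x)) return(rep(0, n))
    if (length(x) != n)
      stop_invalid("unit %s: %s trace has %d samples, expected %d",
                   unit$unit_id, what, length(x), n)
    as.numeric(x)
  }
  light <- fit(unit$light, "light")
  analog <- fit(unit$analog, "analog")
  stim_values <- rep(0, n)
  if (!is.null(unit$stimulus)) {
    cfg <- unit$stimulus
    stim_values <- switch(cfg$kind,
      square = square_stimulus(cfg, duration, dt),
      binary_noise = binary_noise_stimulus(cfg, duration, dt,
                                           light = identical(unit$stimulus_route, "light"))$trace,
      external = fit(cfg$trace, "external stimulus"))
    if (unit$stimulus_route == "light") light <- light + stim_values
    else analog <- analog + stim_values
  }
  i_photo <- if (any(light != 0) || unit$mode$photo_baseline != 0)
    photo_current(light, unit$mode, dt) else rep(0, n)
  i_analog <- analog * unit$dials$input_gain
  i_noise <- noise_current(unit$dials$noise_amplitude, duration, dt,
                           seed = derive_seed(master_seed, unit$unit_id))
  i_static <- rep(unit$dials$static_current, n)
  list(i_photo = i_photo, i_analog = i_analog, i_noise = i_noise,
       i_static = i_static, stimulus = stim_values)
}

#' Run a wired multi-unit simulation
#'
#' Advances all units on a shared clock. Non-synaptic drive (photoreceptor,
#' analog-in, stimulus generator, membrane noise, static current) is resolved
#' per unit up front; synaptic currents evolve during the run: a spike in a
#' source unit at step `k` adds the edge gain to the target port's
#' exponential synapse at step `k + 1` (one-step conduction delay). Each
#' unit's noise stream is derived from the master seed and its id, so adding
#' a unit does not perturb the others. The run is deterministic given the
#' configuration and seed.
#'
#' @param units A list of [unit_spec()] objects (unique ids).
#' @param wiring A [wiring_graph()] (or `NULL` for unconnected units).
#' @param duration Simulated time (ms); must be positive.
#' @param dt Sampling step (ms).
#' @param seed Master seed for all noise streams.
#' @param tau_syn Synaptic decay time constant (ms).
#' @param n_sub Integration substeps per sample (see [step_neuron()]).
#' @return A named list with one [recording_log] per unit.
#' @export
run_simulation <- function(units, wiring = NULL, duration, dt = 1, seed = 1,
                           tau_syn = 10, n_sub = NULL) {
  if (inherits(units, "unit_spec")) units <- list(units)
  stopifnot(length(units) > 0,
            all(vapply(units, inherits, logical(1), "unit_spec")))
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(tau_syn, "tau_syn", positive = TRUE)
  if (is.null(n_sub)) n_sub <- default_n_sub(dt)
  ids <- vapply(units, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids))
    stop_invalid("duplicate unit ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(wiring)) wiring <- wiring_graph()
  stopifnot(inherits(wiring, "wiring_graph"))
  if (nrow(wiring)) {
    missing <- setdiff(c(wiring$src, wiring$dst), ids)
    if (length(missing))
      stop_invalid("wiring references unknown unit(s): %s",
                   paste(missing, collapse = ", "))
    for (k in seq_len(nrow(wiring))) {
      tgt <- units[[match(wiring$dst[k], ids)]]
      if (wiring$port[k] == 1L && !is.null(tgt$stimulus))
        stop_invalid("unit %s: synapse port 1 is occupied by the stimulus generator",
                     wiring$dst[k])
    }
  }

  n <- as.integer(round(duration / dt))
  inputs <- lapply(units, resolve_unit_inputs, n = n, dt = dt,
                   master_seed = seed)
  i_ext <- vapply(inputs, function(x)
    x$i_photo + x$i_analog + x$i_noise + x$i_static, numeric(n))
  i_ext <- matrix(i_ext, nrow = n)

  pars <- t(vapply(units, function(u) {
    st <- resting_state(u$mode, i_hold = u$dials$static_current +
                          u$mode$photo_baseline)
    c(u$mode$a, u$mode$b, u$mode$c, u$mode$d, st$v, st$u)
  }, numeric(6)))

  net <- izh_network_cpp(pars, i_ext,
                         as.integer(match(wiring$src, ids) - 1L),
                         as.integer(match(wiring$dst, ids) - 1L),
                         as.integer(wiring$port), as.numeric(wiring$gain),
                         tau_syn, dt, as.integer(n_sub))

  t <- (seq_len(n) - 1) * dt
  out <- lapply(seq_along(units), function(j) {
    inp <- inputs[[j]]
    log <- data.frame(
      t = t, v = net$v[, j], u = net$u[, j],
      spike = as.integer(net$spiked[, j]),
      i_photo = inp$i_photo,
      i_syn1 = net$i_syn1[, j], i_syn2 = net$i_syn2[, j],
      i_analog = inp$i_analog, i_noise = inp$i_noise,
      i_static = inp$i_static,
      i_total = inp$i_photo + net$i_syn1[, j] + net$i_syn2[, j] +
        inp$i_analog + inp$i_noise + inp$i_static,
      stimulus = inp$stimulus,
      syn1_event = as.integer(net$syn1_event[, j]),
      syn2_event = as.integer(net$syn2_event[, j]))
    recording_log(log, unit_id = ids[j], dt = dt)
  })
  names(out) <- ids
  out
}

#' Recording log of one simulated (or real) unit
#'
#' A tidy per-sample time series mirroring the device's serial stream:
#' timestamps, membrane potential, recovery variable, spike flag, the
#' per-channel current breakdown and its sum, the stimulus value, and
#' incoming-synapse event flags. `t` and `v` are mandatory; other columns
#' may be absent in logs from reduced sources.
#'
#' @param data A `data.frame` with at least columns `t` (ms, uniform
#'   spacing) and `v` (mV).
#' @param unit_id Identifier of the recorded unit.
#' @param dt Sampling step (ms); inferred from `t` when `NULL`.
#' @return The validated `data.frame` with class `recording_log`.
#' @export
recording_log <- function(data, unit_id = "unit", dt = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("t", "v") %in% names(data)))
    stop_invalid("a recording log needs columns `t` and `v`")
  if (nrow(data) < 2) stop_invalid("a recording log needs at least 2 samples")
  dts <- diff(data$t)
  bad <- which(abs(dts - dts[1]) > 1e-9 * max(1, abs(dts[1])))
  if (length(bad))
    stop_invalid("non-uniform time spacing at row %d (t = %g)",
                 bad[1] + 1L, data$t[bad[1] + 1L])
  if (is.null(dt)) dt <- dts[1]
  chan <- c("i_photo", "i_syn1", "i_syn2", "i_analog", "i_noise", "i_static")
  present <- intersect(chan, names(data))
  if ("i_total" %in% names(data) && length(present) == length(chan)) {
    resid <- abs(data$i_total - rowSums(data[present]))
    n_bad <- sum(resid > 1e-6 * pmax(1, abs(data$i_total)))
    if (n_bad > 0)
      warning(sprintf("%d row(s) violate i_total = sum(components); kept",
                      n_bad), call. = FALSE)
  }
  structure(data, class = c("recording_log", "data.frame"),
            unit_id = unit_id, dt = dt)
}

#' @export
print.recording_log <- function(x, ...) {
  cat(sprintf("<recording_log> unit %s: %d samples at dt=%g ms (%g ms), %d spikes\n",
              attr(x, "unit_id"), nrow(x), attr(x, "dt"),
              nrow(x) * attr(x, "dt"),
              if ("spike" %in% names(x)) sum(x$spike) else NA_integer_))
  invisible(x)
}

# Shortest decimal representation that survives a text round trip of the
# double, so write -> read -> write is byte-identical.
format_roundtrip <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  for (digits in c(16L, 17L)) {
    bad <- as.numeric(out) != x
    if (!any(bad)) break
    out[bad] <- formatC(x[bad], digits = digits, format = "g")
  }
  out[x == trunc(x) & abs(x) < 1e15] <-
    sprintf("%.0f", x[x == trunc(x) & abs(x) < 1e15])
  out
}

#' Write a recording log as CSV
#'
#' Comma-separated, '.' decimal, header row naming every field, one row per
#' sample, no quoting. Numeric formatting is chosen so the file round-trips
#' exactly: writing, reading with [read_log()] and writing again produces a
#' byte-identical file.
#'
#' @param log A [recording_log].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "recording_log"))
  cols <- lapply(log, function(col) {
    if (is.numeric(col)) format_roundtrip(as.numeric(col)) else as.character(col)
  })
  lines <- c(paste(names(log), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a recording log CSV
#'
#' Accepts simulator output or any device log with at least `t` and `v`
#' columns (a column subset is tolerated; absent channels are simply
#' missing). Rows violating the `i_total = sum(components)` invariant beyond
#' tolerance raise a warning, not an error; non-uniform time spacing is a
#' format error naming the first offending row.
#'
#' @param path CSV file path.
#' @param unit_id Identifier to attach; defaults to the file name.
#' @return A [recording_log].
#' @export
read_log <- function(path, unit_id = NULL) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  data <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(unit_id))
    unit_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  recording_log(data, unit_id = unit_id)
}
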