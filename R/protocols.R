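# Scripted end-to-end experiments ("protocols"): each runs simulations with
# fixed, documented settings, returns the logs plus analysis tables, and
# carries a set of named qualitative checks of the phenomenon it demonstrates.

#' Names of the registered protocols
#' @return Character vector of protocol names accepted by [run_protocol()].
#' @export
protocol_names <- function() {
  c("manual_explore", "amplitude_tuning", "volley_sr", "synaptic_network",
    "reverse_correlation")
}

rate_in <- function(spike_times, from, to)
  sum(spike_times >= from & spike_times < to) / ((to - from) / 1000)

light_step_trace <- function(dark_ms, light_ms, tail_ms, amp, dt) {
  c(rep(0, round(dark_ms / dt)), rep(amp, round(light_ms / dt)),
    rep(0, round(tail_ms / dt)))
}

protocol_manual_explore <- function(seed, dt, overrides = list()) {
  amp <- overrides$light_amplitude %||% 20
  light <- light_step_trace(1000, 2000, 1000, amp, dt)
  dur <- length(light) * dt
  logs <- run_simulation(
    lapply(1:3, function(m) unit_spec(sprintf("mode%d", m), mode = m,
                                      light = light)),
    duration = dur, dt = dt, seed = seed)
  st <- lapply(logs, detect_spikes)
  summary <- data.frame(
    unit = names(logs),
    onset_rate_hz = vapply(st, rate_in, numeric(1), 1000, 1200),
    late_rate_hz = vapply(st, rate_in, numeric(1), 2800, 3000),
    dark_rate_hz = vapply(st, rate_in, numeric(1), 0, 1000),
    offset_spikes = vapply(st, function(s) sum(s >= 3000 & s < 3200),
                           numeric(1)),
    steady_light_spikes = vapply(st, function(s) sum(s >= 1500 & s < 3000),
                                 numeric(1)))
  checks <- c(
    mode1_adapts = summary$onset_rate_hz[1] > summary$late_rate_hz[1],
    mode2_offset_rebound = summary$offset_spikes[2] >= 1,
    mode2_quiet_in_light = summary$steady_light_spikes[2] <= 1,
    mode3_dark_baseline = summary$dark_rate_hz[3] > 0)
  list(logs = logs, analysis = list(light_step_summary = summary),
       checks = checks)
}

protocol_amplitude_tuning <- function(seed, dt, overrides = list()) {
  gains <- overrides$gains %||% seq(0, 8, by = 1)
  noise_sd <- overrides$noise_sd %||% 1
  n_pulses <- 10
  stim <- stimulus_config("square", rate = 1, duty = 0.25, amplitude = 1)
  onsets <- seq(0, by = 1000, length.out = n_pulses)
  make_log <- function(gain, noise_amplitude = 0) {
    run_simulation(unit_spec("probe", mode = 1,
                             dials = dial_settings(input_gain = gain,
                                                   noise_amplitude = noise_amplitude),
                             stimulus = stim),
                   duration = n_pulses * 1000, dt = dt, seed = seed)[[1]]
  }
  protocol <- list(gains = gains, onsets = onsets, window = 1000)
  curve <- tuning_curves(protocol, function(g) make_log(g))
  # noise comparison at a fixed mid-sweep gain
  gain_fix <- overrides$noise_gain %||% 4
  noisy <- tuning_curves(list(gains = rep(gain_fix, 3), onsets = onsets,
                              window = 1000),
                         function(g) make_log(g, noise_amplitude = noise_sd))
  clean_row <- tuning_curves(list(gains = rep(gain_fix, 3), onsets = onsets,
                                  window = 1000), function(g) make_log(g))
  spk <- curve$mean_count
  lat <- curve$latency[!is.na(curve$latency)]
  checks <- c(
    count_nondecreasing = all(diff(spk) >= 0),
    latency_nonincreasing = length(lat) < 2 || all(diff(lat) <= 1e-9),
    zero_gain_silent = spk[curve$gain == 0][1] == 0,
    noise_jitter_positive = noisy$jitter[1] > 0,
    noise_free_jitter_zero = clean_row$jitter[1] == 0,
    count_stable_under_noise =
      abs(noisy$mean_count[1] - clean_row$mean_count[1]) < 1)
  list(logs = list(), analysis = list(tuning = curve, tuning_noisy = noisy,
                                      tuning_clean = clean_row),
       checks = checks)
}

protocol_volley_sr <- function(seed, dt, overrides = list()) {
  dur <- overrides$duration %||% 20000
  # volley coding: suprathreshold fast periodic drive; the unit skips cycles
  # but stays phase locked
  volley_rate <- overrides$volley_rate %||% 30
  volley <- run_simulation(
    unit_spec("volley", mode = 1,
              stimulus = stimulus_config("square", rate = volley_rate,
                                         amplitude = 8)),
    duration = dur, dt = dt, seed = seed)[[1]]
  vst <- detect_spikes(volley)
  period <- 1000 / volley_rate
  n_cycles <- dur / period
  v_vs <- vector_strength(vst, period)
  v_null <- vs_null_quantile(length(vst), 0.95, 1000, seed = seed)
  volley_tab <- data.frame(rate_hz = volley_rate,
                           spikes_per_cycle = length(vst) / n_cycles,
                           vs = v_vs$vs, vs_null95 = v_null)

  # stochastic resonance: drive hyperpolarised just below threshold, then
  # sweep membrane noise
  sr_rate <- overrides$sr_rate %||% 4
  sr_amp <- overrides$sr_amplitude %||% 2.5
  amplitudes <- overrides$noise_amplitudes %||% c(0, 0.6, 1, 2, 4, 8)
  n_seeds <- overrides$n_seeds %||% 20
  drive <- square_stimulus(stimulus_config("square", rate = sr_rate,
                                           amplitude = sr_amp), dur, dt)
  sweep <- stochastic_resonance_sweep(
    amplitudes, list(params = preset_modes()[[1]], drive = drive,
                     period = 1000 / sr_rate, dt = dt),
    n_seeds = n_seeds, seed = seed)
  mid <- which(sweep$amplitude > 0 & sweep$mean_count > 0)
  best <- attr(sweep, "best_amplitude")
  best_row <- which(sweep$amplitude == best)
  null95_best <- vs_null_quantile(
    max(1, round(sweep$mean_count[best_row])), 0.95, 1000, seed = seed)
  checks <- c(
    volley_skips_cycles = volley_tab$spikes_per_cycle < 1,
    volley_phase_locked = volley_tab$vs > volley_tab$vs_null95,
    sr_silent_without_noise = sweep$mean_count[1] == 0,
    sr_noise_elicits_spikes = length(mid) > 0,
    sr_locking_significant = length(best_row) == 1 &&
      sweep$mean_vs[best_row] > null95_best,
    sr_nonmonotonic = sweep$mean_vs[nrow(sweep)] <
      max(sweep$mean_vs, na.rm = TRUE))
  list(logs = list(volley = volley),
       analysis = list(volley = volley_tab, sr_sweep = sweep),
       checks = checks)
}

protocol_synaptic_network <- function(seed, dt, overrides = list()) {
  # (a) synaptic gain sweep: driver unit A excites/inhibits a tonically
  # firing target B through port 2
  gains <- overrides$gains %||% c(-10, -5, -2, 0, 2, 5, 10)
  dur_a <- 10000
  target_rate <- vapply(gains, function(g) {
    units <- list(
      unit_spec("A", mode = 1,
                stimulus = stimulus_config("square", rate = 2, amplitude = 8)),
      unit_spec("B", mode = 1, dials = dial_settings(static_current = 6)))
    wiring <- if (g == 0) wiring_graph() else wiring_graph("A", "B", 2L, g)
    logs <- run_simulation(units, wiring, duration = dur_a, dt = dt,
                           seed = seed)
    length(detect_spikes(logs$B)) / (dur_a / 1000)
  }, numeric(1))
  gain_tab <- data.frame(gain = gains, target_rate_hz = target_rate)
  baseline <- target_rate[gains == 0][1]

  # (b) two mode-2 units wired to mutually excite each other: a brief kick
  # starts a self-sustained rhythmic burst pattern (a basic CPG)
  cpg_gain <- overrides$cpg_gain %||% 4
  cpg_tau <- overrides$cpg_tau_syn %||% 60
  dur_b <- overrides$cpg_duration %||% 25000
  kick <- c(rep(10, round(200 / dt)), rep(0, round((dur_b - 200) / dt)))
  cpg_logs <- run_simulation(
    list(unit_spec("A", mode = 2, analog = kick),
         unit_spec("B", mode = 2)),
    wiring_graph(c("A", "B"), c("B", "A"), c(1L, 1L), c(cpg_gain, cpg_gain)),
    duration = dur_b, dt = dt, seed = seed, tau_syn = cpg_tau)
  cpg_spikes <- lapply(cpg_logs, detect_spikes)
  burst_count <- function(st, from) {
    st <- st[st >= from]
    if (length(st) < 2) return(0L)
    sum(diff(st) > 50) + 1L
  }
  sustained_to <- function(st, bin = 2000) {
    # last time up to which every 2-s bin since the kick contains a spike
    edges <- seq(1000, dur_b, by = bin)
    filled <- vapply(edges[-length(edges)], function(e)
      any(st >= e & st < e + bin), logical(1))
    if (!all(filled[1])) return(0)
    runs <- cumprod(filled)
    1000 + sum(runs) * bin
  }
  cpg_tab <- data.frame(
    unit = names(cpg_logs),
    n_spikes = vapply(cpg_spikes, length, numeric(1)),
    bursts_last_10s = vapply(cpg_spikes, burst_count, integer(1),
                             from = dur_b - 10000),
    active_until_ms = vapply(cpg_spikes, sustained_to, numeric(1)))
  checks <- c(
    gain_monotone = all(diff(target_rate) >= 0),
    inhibition_suppresses = target_rate[1] < baseline,
    cpg_rhythmic = all(cpg_tab$bursts_last_10s >= 5),
    cpg_sustained_10s = all(cpg_tab$active_until_ms - 1000 >= 10000))
  list(logs = cpg_logs,
       analysis = list(gain_sweep = gain_tab, cpg = cpg_tab),
       checks = checks)
}

protocol_reverse_correlation <- function(seed, dt, overrides = list()) {
  dur <- overrides$duration %||% 300000
  amp <- overrides$light_amplitude %||% 20
  window <- overrides$window %||% 300
  cfg <- stimulus_config("binary_noise", noise_frame_rate = 50,
                         amplitude = amp, seed = seed)
  noise <- binary_noise_stimulus(cfg, dur, dt, light = TRUE)
  slow <- preset_modes()[[1]]
  fast <- mode_params("ON fast-adapting variant", a = slow$a, b = slow$b,
                      c = slow$c, d = slow$d, photo_polarity = 1,
                      photo_adaptation_tau = 50,
                      description = "mode 1 retuned to a rapidly adapting photo current")
  run_one <- function(params) {
    logs <- run_simulation(unit_spec(params$label, mode = params,
                                     stimulus = cfg,
                                     stimulus_route = "light"),
                           duration = dur, dt = dt, seed = seed)
    log <- logs[[1]]
    st <- detect_spikes(log)
    frame_centered <- noise$frame_values - mean(noise$frame_values)
    list(log = log,
         sta = sta(frame_centered, noise$frame_times, st, window),
         sub = subthreshold_filter(noise$trace - mean(noise$trace), log$v,
                                   window, dt))
  }
  slow_res <- run_one(slow)
  fast_res <- run_one(fast)
  filt_tab <- data.frame(
    variant = c("slow", "fast"),
    n_spikes = c(slow_res$sta$n_spikes, fast_res$sta$n_spikes),
    sub_sign_changes = c(filter_sign_changes(slow_res$sub),
                         filter_sign_changes(fast_res$sub)),
    sta_sign_changes = c(filter_sign_changes(slow_res$sta),
                         filter_sign_changes(fast_res$sta)))
  checks <- c(
    slow_subthreshold_monophasic = filt_tab$sub_sign_changes[1] == 0,
    fast_subthreshold_biphasic = filt_tab$sub_sign_changes[2] == 1,
    enough_spikes = all(filt_tab$n_spikes >= 2000))
  list(logs = list(),
       analysis = list(filters = filt_tab,
                       sta_slow = slow_res$sta, sta_fast = fast_res$sta,
                       sub_slow = slow_res$sub, sub_fast = fast_res$sub),
       checks = checks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a registered figure-style protocol
#'
#' Executes one of the scripted experiments end to end (simulation plus
#' analysis) with its documented default settings, optionally writing the
#' recording logs, analysis tables and a manifest to `out_dir`, and
#' optionally evaluating the protocol's built-in qualitative checks.
#'
#' @param name One of [protocol_names()].
#' @param overrides Named list of protocol-specific setting overrides.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param seed Master seed.
#' @param dt Sampling step (ms).
#' @param check Evaluate the protocol's acceptance checks; any failed check
#'   raises an error after reporting.
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with `logs`, `analysis` and named logical
#'   `checks`.
#' @export
run_protocol <- function(name, overrides = list(), out_dir = NULL, seed = 1,
                         dt = 1, check = FALSE, force = FALSE) {
  if (!name %in% protocol_names())
    stop_invalid("unknown protocol '%s'; valid names: %s", name,
                 paste(protocol_names(), collapse = ", "))
  fn <- switch(name,
               manual_explore = protocol_manual_explore,
               amplitude_tuning = protocol_amplitude_tuning,
               volley_sr = protocol_volley_sr,
               synaptic_network = protocol_synaptic_network,
               reverse_correlation = protocol_reverse_correlation)
  res <- fn(seed = seed, dt = dt, overrides = overrides)
  if (!is.null(out_dir)) {
    write_bundle(res, name, out_dir, seed = seed, dt = dt,
                 overrides = overrides, force = force)
  }
  if (check) {
    failed <- names(res$checks)[!res$checks]
    msg <- paste(sprintf("  [%s] %s", ifelse(res$checks, "ok", "FAIL"),
                         names(res$checks)), collapse = "\n")
    message(sprintf("protocol %s checks:\n%s", name, msg))
    if (length(failed))
      stop_invalid("protocol %s: %d check(s) failed: %s", name,
                   length(failed), paste(failed, collapse = ", "))
  }
  invisible(res)
}

write_bundle <- function(res, name, out_dir, seed, dt, overrides, force) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (id in names(res$logs)) {
    p <- file.path(out_dir, sprintf("%s_%s.csv", name, id))
    if (file.exists(p) && !force)
      stop_invalid("output exists (use force = TRUE): %s", p)
    write_log(res$logs[[id]], p)
    paths <- c(paths, p)
  }
  for (an in names(res$analysis)) {
    obj <- res$analysis[[an]]
    if (is.data.frame(obj)) {
      p <- file.path(out_dir, sprintf("%s_%s.csv", name, an))
      if (file.exists(p) && !force)
        stop_invalid("output exists (use force = TRUE): %s", p)
      utils::write.csv(obj, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    } else if (inherits(obj, "linear_filter")) {
      p <- file.path(out_dir, sprintf("%s_%s.csv", name, an))
      if (file.exists(p) && !force)
        stop_invalid("output exists (use force = TRUE): %s", p)
      utils::write.csv(data.frame(lag_ms = obj$lag, value = obj$values),
                       p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  }
  manifest <- list(protocol = name, seed = seed, dt = dt,
                   overrides = overrides,
                   package_version = as.character(utils::packageVersion("spikesim")),
                   files = basename(paths))
  jsonlite::write_json(manifest, file.path(out_dir, sprintf("%s_manifest.json", name)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
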