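# Shared fixtures and independent reference implementations used to check
# the package against brute-force computations.

rs_params <- function() preset_modes()[[1]]   # regular spiking, ON slow

# Plain fine-step Euler reference for the Izhikevich equations, written
# directly from the model definition (independent of the package's C++
# integrator). Returns the spike count for a constant current step.
izh_oracle_count <- function(params, i_amp, duration, h = 0.01) {
  disc <- (5 - params$b)^2 - 0.16 * 140
  v <- if (disc >= 0) (-(5 - params$b) - sqrt(disc)) / 0.08 else params$c
  u <- params$b * v
  n <- round(duration / h)
  count <- 0L
  for (i in seq_len(n)) {
    if (v >= 30) {
      v <- params$c
      u <- u + params$d
      count <- count + 1L
    } else {
      v <- v + 0.5 * h * (0.04 * v^2 + 5 * v + 140 - u + i_amp)
      v <- v + 0.5 * h * (0.04 * v^2 + 5 * v + 140 - u + i_amp)
      u <- u + h * params$a * (params$b * v - u)
      if (v > 30) v <- 30
    }
  }
  count
}

# Linear-nonlinear-Poisson simulation with a known kernel on the stimulus
# frame grid (most-recent-first, like sta()). Returns frame values, frame
# times and spike times.
lnp_simulate <- function(kernel, n_frames, frame_ms = 20, beta = 0.4,
                         base_rate = 0.1, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    s <- sample(c(-1, 1), n_frames, replace = TRUE)
    L <- length(kernel)
    g <- as.numeric(stats::filter(s, kernel, method = "convolution",
                                  sides = 1))
    g[seq_len(L - 1)] <- 0
    rate <- base_rate * exp(beta * g)
    counts <- stats::rpois(n_frames, rate)
    spike_times <- rep((seq_len(n_frames) - 1) * frame_ms, counts) +
      frame_ms / 2
    list(frame_values = s, frame_times = (seq_len(n_frames) - 1) * frame_ms,
         spike_times = sort(spike_times))
  })
}

# A biphasic test kernel on the frame grid, most-recent-first.
biphasic_kernel <- function() c(0.2, 0.9, 1.0, 0.45, -0.3, -0.75, -0.6, -0.25)

withr_like_tempdir <- function() {
  d <- tempfile("spikesim_test_")
  dir.create(d)
  d
}

# Small single-unit run returning its recording log.
quick_log <- function(duration = 2000, dt = 1, mode = 1, seed = 1, ...) {
  run_simulation(unit_spec("u1", mode = mode, ...), duration = duration,
                 dt = dt, seed = seed)[[1]]
}
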