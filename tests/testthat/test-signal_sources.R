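test_that("square stimulus has the configured duty cycle and edges", {
  cfg <- stimulus_config("square", rate = 1, duty = 0.5, amplitude = 1)
  tr <- square_stimulus(cfg, duration = 10000, dt = 1)
  expect_identical(mean(tr > 0), 0.5)          # 50% duty, exactly
  expect_true(all(tr %in% c(0, 1)))
  # rising edge at the start of each period
  edges <- which(diff(c(0, tr)) > 0)
  tr2 <- square_stimulus(stimulus_config("square", rate = 2, amplitude = 1),
                         3000, dt = 1)
  expect_identical(sum(diff(c(0, tr2)) > 0), 6L)
  expect_identical(edges[1], 1L)
  # degenerate rate
  expect_true(all(square_stimulus(stimulus_config("square", rate = 0),
                                  1000, 1) == 0))
})

test_that("binary noise is frame-held, seeded and unbiased", {
  cfg <- stimulus_config("binary_noise", noise_frame_rate = 50,
                         amplitude = 1, seed = 42)
  bn <- binary_noise_stimulus(cfg, duration = 10000, dt = 1)
  expect_length(bn$frame_values, 500)          # 50 frames per second
  expect_identical(bn$trace,
                   binary_noise_stimulus(cfg, 10000, 1)$trace)
  # constant within frames of 20 ms
  expect_identical(bn$trace, rep(bn$frame_values, each = 20))
  # large-sample level statistics (i.i.d. binomial bounds)
  big <- binary_noise_stimulus(
    stimulus_config("binary_noise", noise_frame_rate = 50, amplitude = 1,
                    seed = 7),
    duration = 2e7, dt = 20)
  x <- big$frame_values
  n <- length(x)
  expect_gte(n, 1e6)
  expect_lt(abs(mean(x)), 3 / sqrt(n))
  lag1 <- mean(x[-1] * x[-n])
  expect_lt(abs(lag1), 3 / sqrt(n))
  # light mode shifts levels to {0, amplitude}
  bl <- binary_noise_stimulus(cfg, 1000, 1, light = TRUE)
  expect_true(all(bl$trace %in% c(0, 1)))
  # frame shorter than dt is rejected
  expect_error(binary_noise_stimulus(
    stimulus_config("binary_noise", noise_frame_rate = 2000, seed = 1),
    1000, dt = 1), "frame")
})

test_that("photoreceptor adaptation shapes ON and OFF responses", {
  modes <- preset_modes()
  dt <- 1
  expect_true(all(photo_current(rep(0, 100), modes[[1]], dt) == 0))
  light <- c(rep(0, 500), rep(20, 2000), rep(0, 1000))
  # ON slow: onset peak above (positive) steady state
  i1 <- photo_current(light, modes[[1]], dt)
  onset <- max(i1[501:700]); steady <- i1[2400]
  expect_gt(onset, 0)
  expect_gt(onset / max(steady, 1e-9), 1)
  # OFF fast: positive transient at offset, near-zero steady current in light
  i2 <- photo_current(light, modes[[2]], dt)
  expect_lt(abs(i2[2400]), 0.5)                 # adapted away (tau 50 ms)
  expect_gt(max(i2[2501:2700]), 10)             # rebound at light offset
  # steady state: under constant light adaptation converges to the level
  expect_lt(abs(photo_current(rep(20, 5000), modes[[2]], dt)[5000]), 1e-6)
  expect_error(photo_current(c(-1, 0), modes[[1]], dt), "non-negative")
})

test_that("synapse current is exponential, linear and signed", {
  expect_true(all(synapse_current(numeric(0), 5, 10, 100, 1) == 0))
  # discrete-time (trapezoidal) integral matches g * tau within 2%
  tau <- 10; g <- 3; dt <- 1
  tr <- synapse_current(0, g, tau, 500, dt)
  integral <- (sum(tr) - tr[1] / 2 - tr[length(tr)] / 2) * dt
  expect_lt(abs(integral - g * tau) / (g * tau), 0.02)
  # gain -g mirrors +g exactly
  expect_identical(synapse_current(c(10, 50), -g, tau, 200, dt),
                   -synapse_current(c(10, 50), g, tau, 200, dt))
  # linear superposition of two spike trains
  a <- synapse_current(c(5, 40), g, tau, 200, dt)
  b <- synapse_current(c(20), g, tau, 200, dt)
  both <- synapse_current(c(5, 20, 40), g, tau, 200, dt)
  expect_equal(both, a + b, tolerance = 1e-12)
  expect_error(synapse_current(10, g, tau_syn = 0, 100, 1), "tau")
  expect_error(synapse_current(500, g, tau, duration = 100, dt = 1),
               "duration")
})

test_that("membrane noise has the dialled amplitude and is seeded", {
  expect_true(all(noise_current(0, 1000, 1) == 0))
  x <- noise_current(2.5, 1e5, 1, seed = 11)
  expect_lt(abs(sd(x) - 2.5) / 2.5, 0.05)
  expect_lt(abs(mean(x)), 3 * 2.5 / sqrt(1e5))
  expect_identical(x, noise_current(2.5, 1e5, 1, seed = 11))
  expect_error(noise_current(-1, 100, 1), ">= 0")
})

test_that("current summation preserves components and their sum", {
  n <- 50
  set.seed(3)
  br <- sum_currents(i_photo = rnorm(n), i_noise = rnorm(n),
                     i_static = rep(2, n))
  expect_s3_class(br, "current_breakdown")
  expect_equal(br$i_total,
               br$i_photo + br$i_syn1 + br$i_syn2 + br$i_analog +
                 br$i_noise + br$i_static,
               tolerance = 1e-12)
  one <- sum_currents(i_analog = 1:5)
  expect_identical(one$i_total, as.numeric(1:5))
  zero <- sum_currents(i_photo = rep(0, 4))
  expect_true(all(zero$i_total == 0))
  expect_error(sum_currents(i_photo = 1:3, i_noise = 1:4), "length")
})

test_that("noise distorts spike timing before it changes spike counts", {
  # fixed suprathreshold pulse drive; moderate noise jitters first-spike
  # latency while the per-pulse spike count stays put
  drive <- square_stimulus(stimulus_config("square", rate = 2, duty = 0.25,
                                           amplitude = 8), 5000, 1)
  p <- rs_params()
  clean <- simulate_unit(p, drive)$spike_times
  lat0 <- vapply(seq(0, 4500, 500), function(on) {
    s <- clean[clean >= on & clean < on + 500]
    if (length(s)) s[1] - on else NA_real_
  }, numeric(1))
  counts <- integer(0); lats <- numeric(0)
  for (s in 1:8) {
    noisy <- simulate_unit(p, drive + noise_current(1, 5000, 1, seed = s))
    st <- noisy$spike_times
    per_pulse <- vapply(seq(0, 4500, 500), function(on)
      sum(st >= on & st < on + 500), numeric(1))
    first <- vapply(seq(0, 4500, 500), function(on) {
      x <- st[st >= on & st < on + 500]
      if (length(x)) x[1] - on else NA_real_
    }, numeric(1))
    counts <- c(counts, per_pulse)
    lats <- c(lats, first)
  }
  expect_gt(sd(lats, na.rm = TRUE), 0)           # jitter appears
  expect_lt(abs(mean(counts) - mean(vapply(seq(0, 4500, 500), function(on)
    sum(clean >= on & clean < on + 500), numeric(1)))), 1)
})
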