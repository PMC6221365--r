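test_that("spike detection uses flags when present, threshold otherwise", {
  log <- quick_log(duration = 2000, dials = dial_settings(static_current = 10))
  flagged <- detect_spikes(log)
  expect_identical(flagged, log$t[log$spike > 0])
  expect_gt(length(flagged), 2)
  # strip the flags: upward 0 mV crossings with refractory merge
  bare <- recording_log(log[c("t", "v")], unit_id = "bare")
  fallback <- detect_spikes(bare)
  expect_equal(length(fallback), length(flagged), tolerance = 0.01)
  # synthetic one-spike trace
  v <- rep(-70, 100); v[50] <- 10; v[51] <- 25; v[52] <- -65
  one <- recording_log(data.frame(t = 0:99, v = v), unit_id = "synth")
  expect_length(detect_spikes(one), 1)
  flat <- recording_log(data.frame(t = 0:99, v = rep(-65, 100)), "flat")
  expect_length(detect_spikes(flat), 0)
})

test_that("stimulus alignment averages trials and drops partial ones", {
  log <- quick_log(duration = 5000,
                   stimulus = stimulus_config("square", rate = 1, duty = 0.25,
                                              amplitude = 8))
  al <- align_to_stimulus(log, onsets = seq(0, 4000, 1000), window = 1000)
  expect_identical(al$n_trials, 5L)
  expect_identical(dim(al$v), c(5L, 1000L))
  # deterministic drive: trials repeat (up to the decaying initial
  # transient) and the rasters are exactly stereotyped
  expect_equal(al$v_mean, al$v[1, ], tolerance = 1e-4)
  expect_true(all(vapply(al$rasters, function(r)
    identical(r, al$rasters[[1]]), logical(1))))
  # exactly periodic log: the average equals any single row, exactly
  pat <- c(rep(-70, 80), seq(-70, 20, length.out = 10), rep(-65, 10))
  per <- recording_log(data.frame(t = 0:499, v = rep(pat, 5)), "periodic")
  alp <- align_to_stimulus(per, onsets = seq(0, 400, 100), window = 100)
  expect_identical(alp$v_mean, alp$v[3, ])
  # onsets outside the log are dropped and counted
  al2 <- align_to_stimulus(log, onsets = c(-500, 0, 1000, 4500), window = 1000)
  expect_identical(al2$n_trials, 2L)
  expect_identical(al2$n_dropped, 2L)
  expect_error(align_to_stimulus(log, onsets = 10000, window = 1000),
               "window")
})

test_that("tuning curves capture gain dependence of count and latency", {
  stim <- stimulus_config("square", rate = 1, duty = 0.25, amplitude = 1)
  onsets <- seq(0, 9000, 1000)
  simulate_at <- function(gain, noise = 0) {
    run_simulation(unit_spec("p", mode = 1,
                             dials = dial_settings(input_gain = gain,
                                                   noise_amplitude = noise),
                             stimulus = stim),
                   duration = 10000, dt = 1, seed = 4)[[1]]
  }
  curve <- tuning_curves(list(gains = c(0, 2, 4, 6, 8), onsets = onsets,
                              window = 1000),
                         function(g) simulate_at(g))
  expect_identical(curve$mean_count[1], 0)        # no drive, no spikes
  expect_true(is.na(curve$latency[1]))            # undefined latency flagged
  expect_true(all(diff(curve$mean_count) >= 0))
  lat <- curve$latency[!is.na(curve$latency)]
  expect_true(all(diff(lat) <= 1e-9))
  # noise-free jitter is exactly zero; noise makes it positive
  expect_identical(curve$jitter[curve$gain == 6], 0)
  noisy <- tuning_curves(list(gains = c(6, 6, 6), onsets = onsets,
                              window = 1000),
                         function(g) simulate_at(g, noise = 1))
  expect_gt(noisy$jitter[1], 0)
  expect_error(tuning_curves(list(gains = 1:2, onsets = onsets, window = 1),
                             identity), "3 swept")
})

test_that("vector strength measures phase concentration", {
  expect_equal(vector_strength(c(10, 110, 210), 100)$vs, 1, tolerance = 1e-12)
  expect_equal(vector_strength(c(0, 50), 100)$vs, 0, tolerance = 1e-12)
  expect_equal(vector_strength(c(25, 125), 100)$mean_phase, pi / 2,
               tolerance = 1e-9)
  set.seed(8)
  unif <- runif(1e4, 0, 1e6)
  expect_lt(vector_strength(unif, 100)$vs, 0.03)
  expect_error(vector_strength(numeric(0), 100), "zero spikes")
  # null quantile shrinks roughly as 1/sqrt(n)
  expect_lt(vs_null_quantile(1000, seed = 2), vs_null_quantile(10, seed = 2))
})

test_that("stochastic resonance needs noise and peaks at intermediate noise", {
  drive <- square_stimulus(stimulus_config("square", rate = 4,
                                           amplitude = 2.5), 20000, 1)
  sweep <- stochastic_resonance_sweep(
    c(0, 0.6, 2, 8),
    list(params = rs_params(), drive = drive, period = 250, dt = 1),
    n_seeds = 5, seed = 3)
  expect_identical(sweep$mean_count[1], 0)
  expect_gt(sweep$mean_count[2], 0)
  expect_lt(sweep$mean_vs[4], max(sweep$mean_vs, na.rm = TRUE))
  best <- attr(sweep, "best_amplitude")
  expect_true(best > 0 && best < 8)
  # suprathreshold drive violates the precondition
  expect_error(stochastic_resonance_sweep(
    c(0, 1), list(params = rs_params(), drive = drive * 4, period = 250),
    n_seeds = 2), "not subthreshold")
})

test_that("spike-triggered average recovers a planted impulse", {
  set.seed(12)
  n_frames <- 4000
  frame_ms <- 20
  fv <- sample(c(-1, 1), n_frames, replace = TRUE)
  ft <- (seq_len(n_frames) - 1) * frame_ms
  # spikes exactly 3 frames after every +1 frame
  spk <- ft[which(fv == 1) + 3] + frame_ms / 2
  spk <- spk[!is.na(spk)]
  res <- sta(fv, ft, spk, window = 200)
  expect_equal(res$values[4], 1, tolerance = 1e-12)   # lag 3 frames
  other <- res$values[-4]
  expect_true(all(abs(other) < 3 / sqrt(res$n_spikes)))
  expect_identical(res$lag[4], 3 * frame_ms)
  # early spikes are excluded and counted
  res2 <- sta(fv, ft, c(10, spk), window = 200)
  expect_identical(res2$n_excluded, res$n_excluded + 1L)
  # constant stimulus is flagged uninformative
  flat <- sta(rep(1, 100), (0:99) * 20, c(500, 900), window = 100)
  expect_true(flat$uninformative)
  expect_error(sta(fv, ft, numeric(0), 100), "usable")
})

test_that("sta recovers a known kernel from a linear-nonlinear-Poisson cell", {
  kern <- biphasic_kernel()
  lnp <- lnp_simulate(kern, n_frames = 30000, seed = 21)
  expect_gte(length(lnp$spike_times), 2000)
  res <- sta(lnp$frame_values, lnp$frame_times, lnp$spike_times,
             window = length(kern) * 20)
  r <- cor(res$values[seq_along(kern)], kern)
  expect_gte(r, 0.9)
})

test_that("subthreshold filter is a normalised cross-correlation", {
  set.seed(5)
  s <- sample(c(-1, 1), 20000, replace = TRUE)
  k <- 7
  v <- c(rep(0, k), s[1:(length(s) - k)])      # stimulus delayed by k samples
  res <- subthreshold_filter(s, v, window = 20, dt = 1)
  expect_equal(res$values[k + 1], 1, tolerance = 0.05)
  expect_true(all(abs(res$values[-(k + 1)]) < 0.05))
  # uncorrelated response: all lags inside the sampling noise floor
  v2 <- rnorm(length(s))
  res2 <- subthreshold_filter(s, v2, window = 20, dt = 1)
  expect_true(all(abs(res2$values) < 3 / sqrt(length(s))))
  expect_error(subthreshold_filter(rep(0, 100), rnorm(100), 10), "variance")
  expect_error(subthreshold_filter(s + 10, v, 10), "zero-mean")
})

test_that("slow vs fast photoreceptors give mono- vs biphasic filters", {
  res <- run_protocol("reverse_correlation", seed = 2,
                      overrides = list(duration = 150000))
  tab <- res$analysis$filters
  expect_identical(tab$sub_sign_changes[tab$variant == "slow"], 0L)
  expect_identical(tab$sub_sign_changes[tab$variant == "fast"], 1L)
})

test_that("filter convergence: doubling the data stays within the noise floor", {
  kern <- biphasic_kernel()
  lnp1 <- lnp_simulate(kern, n_frames = 20000, seed = 31)
  lnp2 <- lnp_simulate(kern, n_frames = 40000, seed = 31)
  f1 <- sta(lnp1$frame_values, lnp1$frame_times, lnp1$spike_times,
            window = length(kern) * 20)
  f2 <- sta(lnp2$frame_values, lnp2$frame_times, lnp2$spike_times,
            window = length(kern) * 20)
  floor1 <- 3 / sqrt(f1$n_spikes)
  expect_lt(max(abs(f1$values - f2$values)), 2 * floor1)
})
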