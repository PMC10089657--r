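test_that("trajectory generator recovers the requested shuttle count", {
  mz <- maze_spec("ELM", "CC")
  # degenerate session: stationary at a reward zone
  trk0 <- simulate_trajectory(mz, behaviour_params(n_shuttles = 0, seed = 1))
  expect_gte(nrow(trk0), 1)
  expect_true(all(trk0$x_cm <= mz$reward_zone_length))
  expect_error(behaviour_params(n_shuttles = -1), class = "elmaze_parameter_error")
  expect_error(behaviour_params(frame_rate = 0), class = "elmaze_parameter_error")
  # 10 shuttles, no retreats: exactly 10 rewarded trials per direction
  trk <- simulate_trajectory(mz, behaviour_params(n_shuttles = 10, seed = 4))
  tr <- segment_trials(linearize_elm(trk, mz), mz)
  expect_equal(sum(tr$direction == "right"), 10)
  expect_equal(sum(tr$direction == "left"), 10)
  expect_true(all(tr$rewarded))
})

test_that("positions stay inside the maze and output is seed-deterministic", {
  mz <- maze_spec("ELM", "CO")
  p <- behaviour_params(n_shuttles = 5, retreat_prob = 0.5, seed = 9)
  a <- simulate_trajectory(mz, p)
  b <- simulate_trajectory(mz, p)
  expect_identical(a, b)
  expect_true(all(a$x_cm >= 0 & a$x_cm <= mz$track_length))
  expect_true(all(abs(a$y_cm) <= mz$track_width / 2))
  expect_true(all(is.finite(compute_speed(a)$speed_cms)))
})

test_that("retreat frequency matches the configured probability", {
  mz <- maze_spec("ELM", "CO")
  # accumulate at least 40 open-half entries across seeded sessions
  entries <- list()
  s <- 0
  while (sum(vapply(entries, nrow, integer(1))) < 40) {
    s <- s + 1
    trk <- simulate_trajectory(mz, behaviour_params(n_shuttles = 10,
                                                    retreat_prob = 0.5,
                                                    seed = 100 + s))
    entries[[s]] <- attr(trk, "open_entries")
  }
  flags <- unlist(lapply(entries, function(e) e$retreat))[1:40]
  iv <- binom99(40, 0.5)
  expect_gte(sum(flags), iv[1])
  expect_lte(sum(flags), iv[2])
})

test_that("spike generator realises the specified inhomogeneous Poisson rate", {
  mz <- maze_spec("ELM", "CC")
  # zero rate: empty train
  trk <- simulate_trajectory(mz, behaviour_params(n_shuttles = 2, seed = 2))
  tun0 <- neuron_params(60, 60, peak_rate = 0, baseline_rate = 0, seed = 5)
  expect_length(simulate_spikes(tun0, trk, mz), 0)
  # long dwell at the field centre: empirical rate within 3 Poisson SE
  dwell <- make_tracking(rep(60, 200 * 50))   # 200 s at the centre
  tun <- neuron_params(60, 60, peak_rate = 10, baseline_rate = 0,
                       speed_gain = 0, seed = 6)
  st <- simulate_spikes(tun, dwell, mz)
  rate_hat <- length(st) / 200
  expect_lt(abs(rate_hat - 10), 3 * sqrt(10 / 200))
  # determinism
  expect_identical(simulate_spikes(tun, dwell, mz),
                   simulate_spikes(tun, dwell, mz))
})

test_that("total spike count tracks the integral of the specified rate", {
  mz <- maze_spec("ELM", "CC")
  trk <- simulate_trajectory(mz, behaviour_params(n_shuttles = 8, seed = 3))
  lam <- function(tun, trk) {
    pos <- pmin(pmax(trk$x_cm, 0), mz$track_length)
    dt <- c(diff(trk$time_s), median(diff(trk$time_s)))
    # direction-free expected rate bound: both centres equal here
    sum((tun$baseline_rate +
           tun$peak_rate * exp(-(pos - tun$field_centre_right)^2 /
                                 (2 * tun$field_width^2))) * dt)
  }
  for (s in 1:5) {
    tun <- neuron_params(40, 40, peak_rate = 6, baseline_rate = 1, seed = s)
    st <- simulate_spikes(tun, trk, mz)
    mu <- lam(tun, trk)
    expect_lt(abs(length(st) - mu), 4 * sqrt(mu))
  }
})

test_that("LFP generator embeds detectable ripple-band bursts", {
  # no events requested: none embedded
  l0 <- simulate_lfp(duration_s = 5, swr_rate = 0, seed = 1)
  expect_equal(nrow(l0$events), 0)
  expect_error(simulate_lfp(swr_freq = 100), class = "elmaze_parameter_error")
  # a single 150 Hz, 60 ms, 8 SD burst is found exactly once
  l1 <- simulate_lfp(duration_s = 20, swr_freq = 150, swr_duration_ms = 60,
                     swr_amplitude_sd_units = 8, seed = 7, n_events = 1)
  ev <- detect_swr(l1$trace, l1$fs)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start_s, l1$events$end_s)
  expect_gt(ev$end_s, l1$events$start_s)
  # spectral peak of the burst lies in the ripple band
  idx <- round(l1$events$start_s * l1$fs):round(l1$events$end_s * l1$fs) + 1
  pg <- stats::spec.pgram(l1$trace[idx], taper = 0, plot = FALSE)
  f <- pg$freq * l1$fs
  band <- f >= 100 & f <= 300
  peak_f <- f[band][which.max(pg$spec[band])]
  expect_gte(peak_f, 130)
  expect_lte(peak_f, 230)
})

test_that("session composition honours the remap truth and is reproducible", {
  s0 <- simulate_session(behaviour = behaviour_params(n_shuttles = 3),
                         neurons = population_params(n_neurons = 8,
                                                     remap_to_open_prob = 0),
                         lfp_params = NULL, seed = 21)
  expect_equal(sum(s0$truth$neurons$remap_to_open), 0)
  a <- simulate_session(behaviour = behaviour_params(n_shuttles = 3),
                        neurons = population_params(n_neurons = 6), seed = 5)
  b <- simulate_session(behaviour = behaviour_params(n_shuttles = 3),
                        neurons = population_params(n_neurons = 6), seed = 5)
  expect_identical(a, b)
  # spikes fall inside the tracking span; truth ripples inside the LFP span
  expect_true(all(a$spikes$time_s >= 0 &
                    a$spikes$time_s <= max(a$tracking$time_s) + 0.02))
  expect_true(all(a$truth$swr_events$end_s <=
                    length(a$lfp$trace) / a$lfp$fs))
})
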