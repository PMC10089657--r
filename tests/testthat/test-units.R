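test_that("waveform classification partitions the latency-rate plane", {
  u <- classify_unit(data.frame(trough_to_peak_ms = c(0.5, 0.2, 0.2),
                                mean_rate_hz = c(8, 15, 5)))
  expect_equal(u$cell_class, c("putative_pyramidal", "putative_interneuron",
                               "unclassified"))
  # every grid point gets exactly one label; both thresholds respected
  grid <- expand.grid(lat = seq(0, 1, by = 0.05), rate = seq(0, 40, by = 2))
  g <- classify_unit(data.frame(trough_to_peak_ms = grid$lat,
                                mean_rate_hz = grid$rate))
  expect_true(all(g$cell_class %in% c("putative_pyramidal",
                                      "putative_interneuron",
                                      "unclassified")))
  expect_true(all(g$cell_class[g$trough_to_peak_ms > 0.3 &
                                 g$mean_rate_hz < 20] == "putative_pyramidal"))
  expect_true(all(g$cell_class[g$trough_to_peak_ms < 0.3 &
                                 g$mean_rate_hz >= 10] == "putative_interneuron"))
  # exactly 0.3 ms falls in neither class
  expect_true(all(g$cell_class[g$trough_to_peak_ms == 0.3] == "unclassified"))
  expect_error(classify_unit(data.frame(trough_to_peak_ms = -1,
                                        mean_rate_hz = 5)),
               class = "elmaze_parameter_error")
})

test_that("ripple detection finds constructed bursts with SD-relative thresholds", {
  fs <- 1250
  l <- simulate_lfp(fs = fs, duration_s = 20, swr_freq = 150,
                    swr_duration_ms = 60, swr_amplitude_sd_units = 8,
                    seed = 2, n_events = 1)
  ev <- detect_swr(l$trace, fs)
  expect_equal(nrow(ev), 1)
  expect_lte(ev$start_s, l$events$start_s + 0.02)
  expect_gte(ev$end_s, l$events$end_s - 0.02)
  # two bursts 500 ms apart give two events
  set.seed(5)
  tr <- rnorm(20 * fs)
  burst <- function(at) {
    m <- round(0.06 * fs); idx <- at:(at + m - 1)
    tr[idx] <<- tr[idx] + 8 * 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1))) *
      sin(2 * pi * 150 * (0:(m - 1)) / fs)
  }
  burst(5000); burst(5000 + round(0.5 * fs))
  ev2 <- detect_swr(tr, fs)
  expect_equal(nrow(ev2), 2)
  # amplitude rescaling leaves events untouched
  ev3 <- detect_swr(tr * 37.5, fs)
  expect_equal(ev2, ev3)
  expect_error(detect_swr(rnorm(5), fs), class = "elmaze_insufficient_data")
  expect_error(detect_swr(rnorm(1000), fs = 500), class = "elmaze_parameter_error")
})

test_that("ripple detection stays near-silent on pure noise", {
  # with the 5 SD / 1 SD / 15 ms settings, white noise triggers on the
  # order of one spurious extended excursion per minute (out of ~75000
  # sliding windows examined); anything well beyond that would indicate
  # a thresholding bug
  fs <- 1250
  n_events <- vapply(1:50, function(s) {
    set.seed(s)
    nrow(detect_swr(rnorm(60 * fs), fs))
  }, integer(1))
  expect_lt(mean(n_events), 2)
  expect_lte(stats::median(n_events), 2)
})

test_that("ripple-spike excision matches interval membership", {
  ev <- tibble::tibble(event_id = 1:2, start_s = c(1, 3), peak_s = c(1.05, 3.05),
                       end_s = c(1.1, 3.1), duration_s = 0.1, peak_sd = 6)
  expect_equal(exclude_swr_spikes(c(0.5, 2), ev[0, ]), c(0.5, 2),
               ignore_attr = TRUE)
  out <- exclude_swr_spikes(c(1.0, 1.05, 1.1), ev)
  expect_length(out, 0)
  expect_equal(attr(out, "n_removed"), 3)
  set.seed(8)
  st <- runif(500, 0, 5)
  kept <- exclude_swr_spikes(st, ev)
  oracle <- st[!((st >= 1 & st <= 1.1) | (st >= 3 & st <= 3.1))]
  expect_equal(as.numeric(kept), oracle)
  # data-frame input keeps its shape
  df <- tibble::tibble(unit_id = 1L, time_s = st)
  expect_equal(exclude_swr_spikes(df, ev)$time_s, oracle)
})

test_that("the speed model recovers a planted slope and is orthogonal to speed", {
  set.seed(14)
  n <- 30000
  sp <- tibble::tibble(time_s = (seq_len(n) - 1) * 0.02,
                       speed_cms = pmax(rnorm(n, 20, 8), 0))
  lam <- 0.1 + 0.05 * sp$speed_cms
  counts <- rpois(n, lam)
  st <- rep(sp$time_s, counts) + 0.01   # spikes at bin centres
  fit <- fit_speed_glm(st, sp, bin_width = 0.02)
  expect_lt(abs(fit$coefficients["b1"] - 0.05), 3 * fit$se)
  expect_lt(abs(cor(fit$bins$resid, fit$bins$speed)), 1e-10)
  expect_true(speed_modulation_significant(fit))
  expect_equal(mean(fit$bins$resid), 0, tolerance = 1e-12)
  # tidiers
  expect_equal(nrow(tidy(fit)), 2)
  expect_equal(glance(fit)$b1, unname(fit$coefficients["b1"]))
  # zero-slope, zero-noise spiking is not significant
  sp2 <- sp[1:2000, ]
  st2 <- sp2$time_s + 0.01              # exactly one spike per bin
  fit2 <- fit_speed_glm(st2, sp2)
  expect_false(speed_modulation_significant(fit2))
  expect_error(fit_speed_glm(st2, sp2[1:50, ]),
               class = "elmaze_insufficient_data")
  spc <- sp2; spc$speed_cms <- 10
  expect_error(fit_speed_glm(st2, spc), class = "elmaze_unidentifiable")
})

test_that("residual rate maps match a brute-force assignment oracle", {
  mz <- maze_spec("ELM", "CC")
  trk <- simulate_trajectory(mz, behaviour_params(n_shuttles = 6, seed = 19))
  lp <- linearize_elm(trk, mz)
  st <- simulate_spikes(neuron_params(45, 45, speed_gain = 0.02,
                                      baseline_rate = 1, seed = 20), trk, mz)
  fit <- fit_speed_glm(st, lp)
  rm <- residual_rate_map(fit, lp, mz)
  edges <- seq(0, 120, by = 2.5)
  idx <- findInterval(fit$bins$time_s, lp$time_s, all.inside = TRUE)
  posb <- findInterval(lp$pos_cm[idx], edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  for (b in c(10, 18, 30)) {
    expect_equal(rm$resid_rate[rm$bin == b],
                 sum(fit$bins$resid[posb == b]) /
                   (sum(posb == b) * fit$bin_width))
  }
  # when the slope is zero the residual map is the count map minus its mean
  flat <- structure(list(
    coefficients = c(b0 = mean(fit$bins$count), b1 = 0),
    se = NA_real_, p_value = 1,
    bins = tibble::tibble(time_s = fit$bins$time_s, count = fit$bins$count,
                          speed = fit$bins$speed,
                          fitted = mean(fit$bins$count),
                          resid = fit$bins$count - mean(fit$bins$count)),
    bin_width = fit$bin_width), class = "speed_glm")
  rm0 <- residual_rate_map(flat, lp, mz)
  count_rate <- vapply(seq_len(nrow(rm0)), function(b)
    sum(fit$bins$count[posb == b]) / (sum(posb == b) * fit$bin_width),
    numeric(1))
  off <- mean(fit$bins$count) / fit$bin_width
  v <- rm0$visited
  expect_equal(rm0$resid_rate[v], count_rate[v] - off, tolerance = 1e-9)
})
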