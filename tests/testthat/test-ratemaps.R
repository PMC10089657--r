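test_that("raw rates are spike count over occupancy, exactly", {
  mz <- maze_spec("ELM", "CC")
  # one spike in a bin occupied for 2 s -> 0.5 Hz
  lp <- make_linpos(rep(30, 100))   # 2 s at 30 cm (bin 13)
  m <- linear_rate_map(lp, 0.9, mz, smooth_sd_bins = 0)
  expect_equal(m$rate_raw[m$bin == 13], 1 / m$occupancy_s[m$bin == 13])
  expect_equal(m$n_spikes[m$bin == 13], 1L)
  # zero spikes: all-zero raw map on visited bins
  m0 <- linear_rate_map(lp, numeric(0), mz)
  expect_true(all(m0$rate_raw[m0$visited] == 0))
})

test_that("random sessions match the brute-force binning oracle and conserve spikes", {
  mz <- maze_spec("ELM", "CC")
  trk <- simulate_trajectory(mz, behaviour_params(n_shuttles = 5, seed = 8))
  lp <- linearize_elm(trk, mz)
  st <- simulate_spikes(neuron_params(50, 80, seed = 12), trk, mz)
  m <- linear_rate_map(lp, st, mz, direction = "each")
  # conservation: sum rate_i * occ_i over directions = total spikes, exactly
  expect_identical(sum(m$n_spikes), length(st))
  expect_equal(sum(m$rate_raw * m$occupancy_s, na.rm = TRUE), length(st))
  # oracle: assign each spike to its preceding sample's bin and direction
  edges <- seq(0, 120, by = 2.5)
  sid <- findInterval(st, lp$time_s)
  for (dd in c("right", "left")) {
    md <- m[m$direction == dd, ]
    sel <- lp$direction == dd
    dts <- c(pmin(diff(lp$time_s), 0.5), median(diff(lp$time_s)))
    for (b in c(5, 20, 24, 40)) {
      inbin <- findInterval(lp$pos_cm, edges, rightmost.closed = TRUE,
                            all.inside = TRUE) == b
      occ_o <- sum(dts[sel & inbin])
      nsp_o <- sum(sel[sid] & findInterval(lp$pos_cm[sid], edges,
                                           rightmost.closed = TRUE,
                                           all.inside = TRUE) == b)
      expect_equal(md$occupancy_s[md$bin == b], occ_o)
      expect_equal(md$n_spikes[md$bin == b], nsp_o)
    }
  }
  # p_i sums to one over visited bins
  for (dd in c("right", "left"))
    expect_equal(sum(m$p_occ[m$direction == dd], na.rm = TRUE), 1,
                 tolerance = 1e-12)
})

test_that("mask-aware smoothing preserves the mean rate on interior-supported maps", {
  mz <- maze_spec("ELM", "CC")
  # uniform occupancy, rates supported away from the edges (> 3 SD)
  set.seed(11)
  rate <- c(rep(0, 7), runif(34, 0, 10), rep(0, 7))
  lp <- make_linpos(rep(seq(1.25, 118.75, by = 2.5), each = 20))
  m <- linear_rate_map(lp, numeric(0), mz, smooth_sd_bins = 1)
  m$rate_raw <- rate
  m$rate_smooth <- elmaze:::smooth_masked_1d(rate, m$visited, 1)
  expect_equal(mean(m$rate_smooth[m$visited]), mean(rate),
               tolerance = 1e-9)
})

test_that("2D maps divide spikes by occupancy per 10 cm bin", {
  trk <- make_tracking(rep(c(5, 15, 25), each = 100))
  trk$y_cm <- rep(5, 300)
  st <- c(0.5, 0.7, 2.5)             # two spikes in bin 1's dwell, one in bin 2's
  m <- rate_map_2d(trk, st, bin_cm = 10)
  occ1 <- m$occupancy_s[m$xbin == 1]
  expect_equal(m$n_spikes[m$xbin == 1], 2L)
  expect_equal(m$rate_raw[m$xbin == 1], 2 / occ1)
  expect_equal(sum(m$rate_raw * m$occupancy_s, na.rm = TRUE), 3)
})

test_that("z-transform standardises visited bins and flags constant maps", {
  m <- make_map(c(1, 2, 3, 4, 5))
  z <- z_transform(m, on = "raw")
  expect_equal(mean(z$rate_z), 0, tolerance = 1e-12)
  expect_equal(sd(z$rate_z), 1, tolerance = 1e-12)
  # affine rescaling leaves z-scores unchanged
  m2 <- make_map(3 * c(1, 2, 3, 4, 5) + 7)
  expect_equal(z_transform(m2, on = "raw")$rate_z, z$rate_z,
               tolerance = 1e-12)
  # constant map: zeros plus flag
  zc <- z_transform(make_map(rep(2, 4)), on = "raw")
  expect_true(all(zc$rate_z == 0))
  expect_true(attr(zc, "constant_map"))
  expect_error(z_transform(make_map(1, visited = c(TRUE))),
               class = "elmaze_insufficient_bins")
})

test_that("peak bin is the argmax with low-index tie-breaking", {
  m <- make_map(c(0, 1, 5, 2, 1, 0, 3))
  expect_equal(peak_bin(m, on = "raw"), 3)
  m2 <- make_map(c(0, 1, 5, 2, 1, 0, 5))
  expect_equal(peak_bin(m2, on = "raw"), 3)   # tie -> lowest index
  set.seed(3)
  for (k in 1:20) {
    r <- runif(30)
    mm <- make_map(r)
    expect_equal(peak_bin(mm, on = "raw"), which.max(r))
  }
})

test_that("EPM centre crossings are split into five fixed time bins", {
  geom <- epm_geometry()
  # 1 s crossing with spikes at 0.1 s and 0.9 s into it
  n_arm <- 25
  dat <- tibble::tibble(
    time_s = seq(0, by = 0.02, length.out = n_arm + 50 + n_arm),
    x_cm = c(seq(30, 5, length.out = n_arm), rep(0, 50),
             rep(0, n_arm)),
    y_cm = c(rep(0, n_arm), rep(0, 50), seq(5, 30, length.out = n_arm)),
    region = c(rep("closed1", n_arm), rep("centre", 50),
               rep("open1", n_arm)),
    segment = c(rep("start_arm", n_arm), rep("centre", 50),
                rep("end_arm", n_arm)))
  dat$lin_cm <- ifelse(dat$segment == "start_arm", dat$x_cm,
                       ifelse(dat$segment == "end_arm", dat$y_cm, NA))
  c0 <- dat$time_s[dat$segment == "centre"][1]
  st <- c(c0 + 0.1, c0 + 0.9)
  m <- epm_trajectory_map(dat, st, geom, smooth_sd_bins = 0)
  centre <- m[m$segment == "centre", ]
  expect_equal(nrow(centre), 5)
  expect_equal(centre$rate_raw, c(5, 0, 0, 0, 5), tolerance = 0.06)
  # no spikes anywhere: all-zero map
  m0 <- epm_trajectory_map(dat, numeric(0), geom)
  expect_true(all(m0$rate_raw[m0$visited] == 0))
  # spike conservation across arm and centre bins
  set.seed(4)
  st2 <- sort(runif(30, 0, max(dat$time_s)))
  m2 <- epm_trajectory_map(dat, st2, geom)
  expect_equal(sum(m2$n_spikes), sum(st2 <= max(dat$time_s) + 0.02))
})
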