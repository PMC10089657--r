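test_that("spatial information and sparsity evaluate the printed formulas", {
  # uniform map: zero information, sparsity one
  m <- make_map(rep(3, 10))
  s <- spatial_stats(m)
  expect_equal(s$si_bits, 0, tolerance = 1e-12)
  expect_equal(s$sparsity, 1, tolerance = 1e-12)
  # two equiprobable bins, rates (2, 0): 1 bit/spike, sparsity 0.5
  m2 <- make_map(c(2, 0), p_occ = c(0.5, 0.5))
  s2 <- spatial_stats(m2, coherence = "none")
  expect_equal(s2$si_bits, 1)
  expect_equal(s2$sparsity, 0.5)
  # silent cell: undefined flag, no error
  s0 <- spatial_stats(make_map(rep(0, 5)))
  expect_true(s0$undefined)
  expect_true(is.na(s0$si_bits))
})

test_that("coherence is the Fisher z of the raw-smoothed correlation", {
  # raw (1,2,3) vs smoothed (1,3,2): r = 0.5, Z = 0.5 ln 3
  m <- make_map(c(1, 2, 3), rate_smooth = c(1, 3, 2))
  s <- spatial_stats(m)
  expect_equal(s$coherence_r, 0.5, tolerance = 1e-12)
  expect_equal(s$coherence_z, 0.5 * log(3), tolerance = 1e-12)
  expect_error(spatial_stats(make_map(c(1, 2))),
               class = "elmaze_insufficient_bins")
  # both correlation variants available
  sn <- spatial_stats(make_map(c(1, 5, 2, 8, 3)), neighbour = TRUE)
  expect_true(is.finite(sn$coherence_z))
})

test_that("spatial metrics are invariant under rate rescaling", {
  set.seed(7)
  for (k in 1:25) {
    lam <- runif(20, 0, 8) * stats::rbinom(20, 1, 0.8)
    p <- runif(20); p <- p / sum(p)
    a <- spatial_stats(make_map(lam, p_occ = p), coherence = "none")
    b <- spatial_stats(make_map(lam * 3.7, p_occ = p), coherence = "none")
    expect_equal(a$si_bits, b$si_bits, tolerance = 1e-12)
    expect_equal(a$sparsity, b$sparsity, tolerance = 1e-12)
  }
  # sparsity hits 1 iff the map is constant over visited bins
  expect_equal(spatial_stats(make_map(rep(2.2, 8)))$sparsity, 1,
               tolerance = 1e-9)
  expect_lt(spatial_stats(make_map(c(rep(2.2, 7), 9)))$sparsity, 1 - 1e-9)
})

test_that("PFS is the Spearman correlation over commonly visited bins", {
  m1 <- z_transform(make_map(c(1, 4, 2, 8, 5)), on = "raw")
  expect_equal(pfs(m1, m1)$pfs, 1)
  m_rev <- z_transform(make_map(c(8, 5, 4, 2, 1)), on = "raw")
  m_fwd <- z_transform(make_map(c(1, 2, 4, 5, 8)), on = "raw")
  expect_equal(pfs(m_fwd, m_rev)$pfs, -1)
  # only bins visited in both directions enter
  ma <- z_transform(make_map(c(1, 4, 2, 8, 5), visited = c(TRUE, TRUE, TRUE, TRUE, FALSE)), on = "raw")
  mb <- z_transform(make_map(c(2, 3, 7, 1, 9), visited = c(FALSE, TRUE, TRUE, TRUE, TRUE)), on = "raw")
  expect_equal(pfs(ma, mb)$n_bins_used, 3)
  # symmetry and invariance under common monotone transforms
  set.seed(21)
  for (k in 1:25) {
    a <- runif(15); b <- runif(15)
    za <- z_transform(make_map(a), on = "raw")
    zb <- z_transform(make_map(b), on = "raw")
    v <- pfs(za, zb)$pfs
    expect_equal(v, pfs(zb, za)$pfs, tolerance = 1e-12)
    expect_equal(v, spearman_oracle(a, b), tolerance = 1e-12)
    zam <- z_transform(make_map(exp(2 * a)), on = "raw")
    zbm <- z_transform(make_map(exp(2 * b)), on = "raw")
    expect_equal(pfs(zam, zbm)$pfs, v, tolerance = 1e-12)
  }
  # constant map: undefined, not an error
  zc <- z_transform(make_map(rep(1, 5)), on = "raw")
  expect_true(pfs(zc, m1)$undefined)
  expect_error(pfs(z_transform(make_map(c(1, 2)), on = "raw"),
                   z_transform(make_map(c(2, 1)), on = "raw")),
               class = "elmaze_insufficient_bins")
})

test_that("the rate-remapping score is the normalised mean-rate difference", {
  m <- make_map(c(2, 2, 2))
  expect_equal(rate_remapping_score(m, m)$score, 0)
  expect_equal(rate_remapping_score(m, make_map(rep(0, 3)))$score, 1)
  # mean rates 2 and 6 Hz -> 0.5
  expect_equal(rate_remapping_score(make_map(rep(2, 4)),
                                    make_map(rep(6, 4)))$score, 0.5)
  expect_true(rate_remapping_score(make_map(rep(0, 3)),
                                   make_map(rep(0, 3)))$undefined)
})

test_that("peak density divides peak counts by active-neuron counts", {
  peaks <- tibble::tibble(
    unit_id = 1:120,
    peak_bin = c(rep(1L, 20), rep(2L, 5), rep(3L, 95)),
    active_bins = c(replicate(100, c(1L, 3L), simplify = FALSE),
                    replicate(10, c(2L, 3L), simplify = FALSE),
                    replicate(10, 3L, simplify = FALSE)))
  # make the first 100 neurons active in bins {1,3}, next 10 in {2,3}
  peaks$peak_bin <- c(rep(1L, 20), rep(3L, 80), rep(2L, 5), rep(3L, 15))
  d <- peak_density(peaks, 4)
  expect_equal(d$density[1], 0.2)    # 20 peaks / 100 active
  expect_equal(d$density[2], 0.5)    # 5 peaks / 10 active
  expect_true(is.na(d$density[4]))   # nobody active there
  expect_true(all(d$n_peaks <= d$n_active))
  bad <- peaks; bad$peak_bin[1] <- 4L
  expect_error(peak_density(bad, 4), class = "elmaze_consistency_error")
})

test_that("the peak-density bootstrap flags concentrated peaks and is seeded", {
  # all 50 neurons peak in bin 2 while active everywhere: flagged
  peaks <- tibble::tibble(unit_id = 1:50, peak_bin = 2L,
                          active_bins = replicate(50, 1:10, simplify = FALSE))
  bt <- peak_density_bootstrap(peaks, 10, n_shuffles = 500, seed = 3)
  expect_true(bt$significant[2])
  bt2 <- peak_density_bootstrap(peaks, 10, n_shuffles = 500, seed = 3)
  expect_identical(bt$significant, bt2$significant)
  expect_identical(bt$null_quantile, bt2$null_quantile)
  expect_warning(peak_density_bootstrap(peaks, 10, n_shuffles = 50, seed = 1))
  expect_error(peak_density_bootstrap(peaks, 10), class = "elmaze_parameter_error")
  # tidiers
  td <- tidy(bt)
  expect_true(all(c("density", "null_quantile", "significant") %in% names(td)))
  expect_equal(glance(bt)$n_significant, sum(bt$significant))
})
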