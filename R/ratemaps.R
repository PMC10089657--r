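# Occupancy and rate maps. Conventions shared by all map builders:
#  - each tracking sample contributes its following inter-sample interval
#    (capped at 0.5 s across dropouts; the last sample contributes the
#    median interval) to the bin it falls in;
#  - a spike is assigned the bin of the last tracking sample at or before
#    it (zero-order hold), so every spike lands in an occupied bin and the
#    identity sum_i rate_i * occupancy_i == total spike count is exact;
#  - bins are half-open [lo, hi), the last bin closed at the track end;
#  - bins with less than `min_occupancy_s` of occupancy are flagged
#    unvisited and excluded from metrics (rates are still reported where
#    occupancy > 0);
#  - smoothing is a truncated Gaussian (3 SD) renormalised over the
#    visited mask, so edge and masked bins do not leak zeros.

sample_dt <- function(t) {
  if (length(t) == 1) return(1)
  dt <- pmin(diff(t), 0.5)
  c(dt, median(dt))
}

# Gaussian mask-renormalised smoothing of a vector of bin values.
smooth_masked_1d <- function(x, mask, sd_bins) {
  n <- length(x)
  if (sd_bins <= 0) return(ifelse(mask, x, NA_real_))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-d^2 / (2 * sd_bins^2))
  K[d > 3 * sd_bins] <- 0
  xm <- ifelse(mask, x, 0)
  num <- as.numeric(K %*% xm)
  den <- as.numeric(K %*% as.numeric(mask))
  out <- ifelse(mask & den > 0, num / den, NA_real_)
  out
}

# Same for a 2D grid given integer bin coordinates (separable kernel).
smooth_masked_2d <- function(x, bx, by, mask, sd_bins) {
  if (sd_bins <= 0) return(ifelse(mask, x, NA_real_))
  dx <- abs(outer(bx, bx, "-")); dy <- abs(outer(by, by, "-"))
  K <- exp(-(dx^2 + dy^2) / (2 * sd_bins^2))
  K[dx > 3 * sd_bins | dy > 3 * sd_bins] <- 0
  xm <- ifelse(mask, x, 0)
  num <- as.numeric(K %*% xm)
  den <- as.numeric(K %*% as.numeric(mask))
  ifelse(mask & den > 0, num / den, NA_real_)
}

#' Linear occupancy-normalised firing-rate map
#'
#' Bins linearised positions (default 2.5 cm bins on the ELM), sums spikes
#' and occupancy per bin and running direction, and smooths with a 1D
#' Gaussian. `p_occ` is the occupancy probability over visited bins (sums
#' to 1 per direction); the occupancy-weighted mean of the raw rates
#' equals the unit's overall rate.
#'
#' @param linpos Output of [linearize_elm()] (`time_s, pos_cm, direction`).
#' @param spike_times Numeric vector of spike times (s).
#' @param maze The ELM [maze_spec()] (provides the track length).
#' @param direction `"both"` pools directions; `"right"`/`"left"` restrict
#'   to one; `"each"` returns both as separate rows.
#' @param bin_width Spatial bin (cm), default 2.5.
#' @param smooth_sd_bins Gaussian SD in bins (default 1; 0 disables).
#' @param min_occupancy_s Occupancy below which a bin is unvisited.
#' @return Tibble of class `linear_rate_map`: `direction, bin, lo_cm,
#'   hi_cm, occupancy_s, p_occ, n_spikes, rate_raw, rate_smooth, visited`.
#' @export
linear_rate_map <- function(linpos, spike_times, maze, direction = "both",
                            bin_width = 2.5, smooth_sd_bins = 1,
                            min_occupancy_s = 0.1) {
  direction <- match.arg(direction, c("both", "right", "left", "each"))
  dirs <- switch(direction, both = list(c("right", "left")),
                 right = list("right"), left = list("left"),
                 each = list("right", "left"))
  edges <- linear_bin_edges(maze$track_length, bin_width)
  nb <- length(edges) - 1L
  dt <- sample_dt(linpos$time_s)
  spike_times <- sort(spike_times)
  sidx <- findInterval(spike_times, linpos$time_s)   # preceding sample
  keep_sp <- sidx >= 1 & spike_times <= max(linpos$time_s) + dt[length(dt)]
  out <- lapply(dirs, function(dd) {
    sel <- linpos$direction %in% dd
    if (!any(sel))
      abort(paste0("no samples in requested direction (",
                   paste(dd, collapse = "/"), ")."),
            class = "elmaze_empty_map")
    bins <- bin_index(linpos$pos_cm, edges)
    occ <- vapply(seq_len(nb), function(b) sum(dt[sel & bins == b]), numeric(1))
    sp_ok <- keep_sp & sel[pmax(sidx, 1)]
    spb <- bins[sidx[sp_ok]]
    nsp <- tabulate(spb, nbins = nb)
    visited <- occ >= min_occupancy_s
    rate_raw <- ifelse(occ > 0, nsp / occ, NA_real_)
    p_occ <- ifelse(visited, occ / sum(occ[visited]), NA_real_)
    rate_smooth <- smooth_masked_1d(ifelse(is.na(rate_raw), 0, rate_raw),
                                    visited, smooth_sd_bins)
    tibble(direction = if (length(dd) > 1) "both" else dd,
           bin = seq_len(nb), lo_cm = edges[-length(edges)], hi_cm = edges[-1],
           occupancy_s = occ, p_occ = p_occ, n_spikes = nsp,
           rate_raw = rate_raw, rate_smooth = rate_smooth, visited = visited)
  })
  res <- bind_rows(out)
  if (all(!res$visited)) abort("all bins unvisited.", class = "elmaze_empty_map")
  class(res) <- c("linear_rate_map", class(tibble()))
  res
}

#' 2D occupancy-normalised firing-rate map
#'
#' Grids the arena into square bins (default 10 x 10 cm) anchored at the
#' minimum tracked coordinates, divides per-bin spike counts by per-bin
#' occupancy seconds, and smooths with a mask-renormalised 2D Gaussian.
#'
#' @param tracking Tracking data frame (`time_s, x_cm, y_cm`, optional
#'   `valid`).
#' @param spike_times Spike times (s).
#' @param bin_cm Square bin side (cm), default 10.
#' @param smooth_sd_bins Gaussian SD in bins.
#' @param min_occupancy_s Occupancy threshold for the visited mask.
#' @return Tibble of class `rate_map_2d`: `xbin, ybin, x_lo, y_lo,
#'   occupancy_s, p_occ, n_spikes, rate_raw, rate_smooth, visited`.
#' @export
rate_map_2d <- function(tracking, spike_times, bin_cm = 10,
                        smooth_sd_bins = 1, min_occupancy_s = 0.1) {
  tracking <- as_tibble(tracking)
  if ("valid" %in% names(tracking)) tracking <- tracking[tracking$valid, ]
  if (nrow(tracking) == 0) abort("empty tracking.", class = "elmaze_empty_map")
  x0 <- min(tracking$x_cm); y0 <- min(tracking$y_cm)
  xb <- pmax(1L, as.integer(ceiling((tracking$x_cm - x0) / bin_cm + 1e-12)))
  yb <- pmax(1L, as.integer(ceiling((tracking$y_cm - y0) / bin_cm + 1e-12)))
  xb[tracking$x_cm == x0] <- 1L; yb[tracking$y_cm == y0] <- 1L
  nx <- max(xb); ny <- max(yb)
  dt <- sample_dt(tracking$time_s)
  cell <- (xb - 1L) * ny + yb
  occ <- numeric(nx * ny)
  agg <- tapply(dt, cell, sum)
  occ[as.integer(names(agg))] <- agg
  spike_times <- sort(spike_times)
  sidx <- findInterval(spike_times, tracking$time_s)
  sidx <- sidx[sidx >= 1]
  nsp <- tabulate(cell[sidx], nbins = nx * ny)
  visited <- occ >= min_occupancy_s
  if (!any(visited)) abort("all bins unvisited.", class = "elmaze_empty_map")
  rate_raw <- ifelse(occ > 0, nsp / occ, NA_real_)
  grid <- expand.grid(ybin = seq_len(ny), xbin = seq_len(nx))
  rate_smooth <- smooth_masked_2d(ifelse(is.na(rate_raw), 0, rate_raw),
                                  grid$xbin, grid$ybin, visited, smooth_sd_bins)
  res <- tibble(xbin = grid$xbin, ybin = grid$ybin,
                x_lo = x0 + (grid$xbin - 1) * bin_cm,
                y_lo = y0 + (grid$ybin - 1) * bin_cm,
                occupancy_s = occ, p_occ = ifelse(visited, occ / sum(occ[visited]), NA_real_),
                n_spikes = nsp, rate_raw = rate_raw, rate_smooth = rate_smooth,
                visited = visited)
  class(res) <- c("rate_map_2d", class(tibble()))
  res
}

#' Rate map along an elevated-plus-maze trajectory
#'
#' Arm segments are binned by space (default 5 cm along the arm's linear
#' coordinate, from the centre edge to the arm end); because crossing
#' paths through the centre vary, the centre segment is instead divided
#' into five fixed time bins spanning the crossing, each with rate
#' `spikes / (crossing duration / 5)`. The concatenated
#' start-arm/centre/end-arm map is smoothed with a 1D Gaussian.
#'
#' @param trajectory One row of [linearize_epm_trajectory()] output (or
#'   its `data` tibble).
#' @param spike_times Spike times (s).
#' @param geom The [epm_geometry()].
#' @param bin_cm Arm spatial bin (cm), default 5.
#' @param n_centre_bins Fixed centre time bins, default 5.
#' @param smooth_sd_bins Gaussian SD (bins) for the concatenated map.
#' @return Tibble `segment, bin, lo, hi, occupancy_s, n_spikes, rate_raw,
#'   rate_smooth, visited` where `lo`/`hi` are cm for arms and seconds for
#'   centre bins.
#' @export
epm_trajectory_map <- function(trajectory, spike_times, geom, bin_cm = 5,
                               n_centre_bins = 5, smooth_sd_bins = 1) {
  dat <- if (is.data.frame(trajectory) && "data" %in% names(trajectory))
    trajectory$data[[1]] else trajectory
  if (!any(dat$segment == "centre"))
    abort("trajectory has no centre crossing.", class = "elmaze_degenerate_crossing")
  ct <- dat$time_s[dat$segment == "centre"]
  c0 <- min(ct); c1 <- max(ct)
  if (c1 <= c0) abort("zero-duration centre crossing.",
                      class = "elmaze_degenerate_crossing")
  dt <- sample_dt(dat$time_s)
  spike_times <- sort(spike_times)
  sidx <- findInterval(spike_times, dat$time_s)
  in_traj <- sidx >= 1 & spike_times <= max(dat$time_s) + dt[length(dt)]
  sseg <- rep(NA_character_, length(spike_times))
  sseg[in_traj] <- dat$segment[sidx[in_traj]]
  hw <- geom$centre_halfwidth
  arm_edges <- seq(hw, hw + geom$arm_length + bin_cm - 1e-9, by = bin_cm)
  arm_part <- function(segname) {
    sel <- dat$segment == segname
    if (!any(sel)) return(NULL)
    bins <- bin_index(dat$lin_cm[sel], arm_edges)
    nb <- length(arm_edges) - 1L
    occ <- vapply(seq_len(nb), function(b) sum(dt[sel][bins == b]), numeric(1))
    sp <- spike_times[!is.na(sseg) & sseg == segname]
    spb <- bin_index(dat$lin_cm[sidx[match(sp, spike_times)]], arm_edges)
    nsp <- tabulate(spb, nbins = nb)
    tibble(segment = segname, bin = seq_len(nb),
           lo = arm_edges[-length(arm_edges)], hi = arm_edges[-1],
           occupancy_s = occ, n_spikes = nsp,
           rate_raw = ifelse(occ > 0, nsp / occ, NA_real_),
           visited = occ > 0)
  }
  dur <- (c1 - c0) / n_centre_bins
  tedges <- seq(c0, c1, length.out = n_centre_bins + 1)
  csp <- spike_times[!is.na(sseg) & sseg == "centre"]
  cbin <- findInterval(csp, tedges, rightmost.closed = TRUE, all.inside = TRUE)
  centre <- tibble(segment = "centre", bin = seq_len(n_centre_bins),
                   lo = tedges[-length(tedges)], hi = tedges[-1],
                   occupancy_s = dur, n_spikes = tabulate(cbin, nbins = n_centre_bins),
                   rate_raw = tabulate(cbin, nbins = n_centre_bins) / dur,
                   visited = TRUE)
  res <- bind_rows(arm_part("start_arm"), centre, arm_part("end_arm"))
  res$rate_smooth <- smooth_masked_1d(ifelse(is.na(res$rate_raw), 0, res$rate_raw),
                                      res$visited, smooth_sd_bins)
  res
}

#' Z-transform a rate map
#'
#' Standardises the map over its visited bins: `(rate - mean) / SD`.
#' Constant maps return zeros with attribute `constant_map = TRUE`
#' (the SD = 0 convention).
#'
#' @param map A `linear_rate_map` (single direction) or any tibble with
#'   `visited` and the chosen rate column.
#' @param on `"smooth"` (default) or `"raw"`: which rates to standardise.
#' @return The map with an added `rate_z` column.
#' @export
z_transform <- function(map, on = c("smooth", "raw")) {
  on <- match.arg(on)
  col <- if (on == "smooth") "rate_smooth" else "rate_raw"
  v <- map$visited
  if (sum(v) < 2) abort("need at least 2 visited bins to z-transform.",
                        class = "elmaze_insufficient_bins")
  x <- map[[col]][v]
  s <- sd(x)
  z <- rep(NA_real_, nrow(map))
  if (is.na(s) || s == 0) {
    z[v] <- 0
    attr(map, "constant_map") <- TRUE
  } else {
    z[v] <- (x - mean(x)) / s
    attr(map, "constant_map") <- FALSE
  }
  map$rate_z <- z
  map
}

#' Bin index of the peak firing rate
#'
#' The argmax of the smoothed rate over visited bins; ties are broken to
#' the lowest bin index.
#'
#' @param map A `linear_rate_map` holding a single direction (or any
#'   tibble with `bin`, `visited` and the chosen rate column).
#' @param on `"smooth"` (default) or `"raw"`.
#' @return Integer bin index.
#' @export
peak_bin <- function(map, on = c("smooth", "raw")) {
  on <- match.arg(on)
  if ("direction" %in% names(map) && length(unique(map$direction)) > 1)
    abort("map contains multiple directions; filter to one first.",
          class = "elmaze_parameter_error")
  col <- if (on == "smooth") "rate_smooth" else "rate_raw"
  v <- which(map$visited & !is.na(map[[col]]))
  if (length(v) == 0) abort("all bins masked.", class = "elmaze_empty_map")
  map$bin[v[which.max(map[[col]][v])]]
}
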