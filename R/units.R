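#' Classify units from waveform statistics
#'
#' Putative pyramidal cells have a trough-to-peak latency above 0.3 ms
#' and a mean firing rate below 20 Hz; putative interneurons a latency
#' below 0.3 ms and a rate of at least 10 Hz. Units falling in neither
#' region (including a latency of exactly 0.3 ms) are unclassified but
#' retained for analyses that do not split by cell class.
#'
#' @param units Data frame with `trough_to_peak_ms` and `mean_rate_hz`
#'   columns (one row per unit).
#' @return The input tibble with a `cell_class` column
#'   (`putative_pyramidal` / `putative_interneuron` / `unclassified`).
#' @examples
#' classify_unit(data.frame(trough_to_peak_ms = c(0.5, 0.2, 0.2),
#'                          mean_rate_hz = c(8, 15, 5)))
#' @export
classify_unit <- function(units) {
  units <- as_tibble(units)
  lat <- units$trough_to_peak_ms; rate <- units$mean_rate_hz
  if (any(!is.finite(lat)) || any(!is.finite(rate)) || any(lat < 0) || any(rate < 0))
    abort("waveform statistics must be finite and non-negative.",
          class = "elmaze_parameter_error")
  units$cell_class <- ifelse(
    lat > 0.3 & rate < 20, "putative_pyramidal",
    ifelse(lat < 0.3 & rate >= 10, "putative_interneuron", "unclassified"))
  units
}

#' Detect sharp-wave ripples in an LFP trace
#'
#' Band-passes the signal between 130 and 230 Hz (4th-order Butterworth,
#' zero-phase forward-backward), computes the root-mean-square amplitude
#' in 10 ms sliding windows (one-sample step), and takes the mean and SD
#' of the whole RMS trace. Samples exceeding `mean + detect_sd * SD` seed
#' events, which are extended outward to the `mean + boundary_sd * SD`
#' crossings. Events separated by less than `merge_gap_s` are merged and
#' events shorter than `min_duration_s` dropped (an automated stand-in
#' for manual artefact curation). Thresholds are SD-relative, so
#' rescaling the trace leaves the events unchanged.
#'
#' @param lfp Numeric LFP trace, or a data frame with an `lfp` column.
#' @param fs Sampling rate (Hz); must be at least 600 Hz.
#' @param t0 Time of the first sample (s).
#' @param band Pass band (Hz), default `c(130, 230)`.
#' @param rms_window_s RMS window (s), default 0.010.
#' @param detect_sd,boundary_sd Detection and boundary thresholds in SD.
#' @param merge_gap_s,min_duration_s Event merging/pruning parameters.
#' @param filter_order Butterworth order (default 4).
#' @return Tibble `event_id, start_s, peak_s, end_s, duration_s,
#'   peak_sd` (peak RMS amplitude in SD units above the mean).
#' @export
detect_swr <- function(lfp, fs, t0 = 0, band = c(130, 230),
                       rms_window_s = 0.010, detect_sd = 5, boundary_sd = 1,
                       merge_gap_s = 0.020, min_duration_s = 0.015,
                       filter_order = 4) {
  if (is.data.frame(lfp)) lfp <- lfp$lfp
  if (fs < 600) abort("sampling rate must be >= 600 Hz for a 130-230 Hz band.",
                      class = "elmaze_parameter_error")
  n <- length(lfp)
  wlen <- max(3L, round(fs * rms_window_s))
  if (n < wlen) abort("trace shorter than the RMS window.",
                      class = "elmaze_insufficient_data")
  bf <- signal::butter(filter_order, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, lfp)
  rms <- sqrt(boxcar(filt^2, wlen))
  m <- mean(rms); s <- sd(rms)
  core <- rms > m + detect_sd * s
  if (!any(core)) return(empty_swr())
  low <- rms <= m + boundary_sd * s
  r <- rle(core)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cs <- starts[r$values]; ce <- ends[r$values]
  low_idx <- which(low)
  ev_start <- vapply(cs, function(i) {
    j <- low_idx[low_idx < i]
    if (length(j)) max(j) + 1L else 1L
  }, integer(1))
  ev_end <- vapply(ce, function(i) {
    j <- low_idx[low_idx > i]
    if (length(j)) min(j) - 1L else n
  }, integer(1))
  ev <- unique(data.frame(start = ev_start, end = ev_end))
  ev <- ev[order(ev$start), , drop = FALSE]
  # merge events closer than merge_gap_s
  merged <- list(); cur <- ev[1, ]
  gap <- merge_gap_s * fs
  if (nrow(ev) > 1) for (k in 2:nrow(ev)) {
    if (ev$start[k] - cur$end <= gap) cur$end <- max(cur$end, ev$end[k])
    else { merged[[length(merged) + 1L]] <- cur; cur <- ev[k, ] }
  }
  merged[[length(merged) + 1L]] <- cur
  ev <- do.call(rbind, merged)
  keep <- (ev$end - ev$start + 1L) / fs >= min_duration_s
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0) return(empty_swr())
  pk <- vapply(seq_len(nrow(ev)), function(k) {
    idx <- ev$start[k]:ev$end[k]
    idx[which.max(rms[idx])]
  }, integer(1))
  tibble(event_id = seq_len(nrow(ev)),
         start_s = t0 + (ev$start - 1) / fs,
         peak_s = t0 + (pk - 1) / fs,
         end_s = t0 + (ev$end - 1) / fs,
         duration_s = (ev$end - ev$start) / fs,
         peak_sd = (rms[pk] - m) / s)
}

empty_swr <- function() {
  tibble(event_id = integer(), start_s = numeric(), peak_s = numeric(),
         end_s = numeric(), duration_s = numeric(), peak_sd = numeric())
}

#' Remove ripple-associated spikes
#'
#' Drops every spike whose time falls inside any detected sharp-wave
#' ripple event (boundaries inclusive). Used as a confound control:
#' ripple-locked population bursts are not place-related firing.
#'
#' @param spikes Data frame with a `time_s` column (e.g. `unit_id,
#'   time_s`), or a bare numeric vector of spike times.
#' @param events [detect_swr()] output (`start_s`, `end_s`).
#' @return The surviving spikes, same shape as the input, with attribute
#'   `n_removed`.
#' @export
exclude_swr_spikes <- function(spikes, events) {
  times <- if (is.data.frame(spikes)) spikes$time_s else spikes
  inside <- rep(FALSE, length(times))
  for (k in seq_len(nrow(events)))
    inside <- inside | (times >= events$start_s[k] & times <= events$end_s[k])
  out <- if (is.data.frame(spikes)) spikes[!inside, ] else spikes[!inside]
  attr(out, "n_removed") <- sum(inside)
  out
}

#' Linear model of spike counts on running speed
#'
#' Bins a unit's spike train at the tracking frame interval (default
#' 20 ms), interpolates the instantaneous speed to the bin centres, and
#' fits `count_t = b0 + b1 * speed_t` by ordinary least squares. The
#' residuals are the speed-controlled spike activity used for
#' residualised rate maps (per-bin residual rates can be negative; this
#' does not affect z-scored analyses).
#'
#' @param spike_times Spike times (s) of one unit.
#' @param speed Data frame with `time_s` and `speed_cms` (e.g.
#'   [compute_speed()] or [linearize_elm()] output).
#' @param bin_width Time bin (s), default 0.02.
#' @return Object of class `speed_glm` with elements `coefficients`
#'   (`b0`, `b1`), `se`, `p_value` (two-sided t-test on `b1`),
#'   `bins` (tibble `time_s, count, speed, fitted, resid`), `bin_width`.
#' @export
fit_speed_glm <- function(spike_times, speed, bin_width = 0.02) {
  sp <- speed[!is.na(speed$speed_cms), ]
  t0 <- min(sp$time_s); t1 <- max(sp$time_s)
  edges <- seq(t0, t1, by = bin_width)
  if (length(edges) < 101)
    abort("need at least 100 time bins to fit the speed model.",
          class = "elmaze_insufficient_data")
  centres <- edges[-length(edges)] + bin_width / 2
  counts <- tabulate(findInterval(spike_times, edges,
                                  rightmost.closed = TRUE, all.inside = FALSE),
                     nbins = length(edges) - 1L)
  counts[1] <- counts[1] + sum(spike_times == t0)  # findInterval edge
  sbin <- approx(sp$time_s, sp$speed_cms, xout = centres, rule = 2)$y
  if (var(sbin) == 0)
    abort("speed is constant: slope unidentifiable.",
          class = "elmaze_unidentifiable")
  fit <- lm(counts ~ sbin)
  sm <- summary(fit)
  structure(list(
    coefficients = c(b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2])),
    se = unname(sm$coefficients[2, 2]),
    p_value = unname(sm$coefficients[2, 4]),
    bins = tibble(time_s = centres, count = counts, speed = sbin,
                  fitted = unname(fit$fitted.values),
                  resid = unname(fit$residuals)),
    bin_width = bin_width
  ), class = "speed_glm")
}

#' @export
print.speed_glm <- function(x, ...) {
  cat(sprintf("<speed_glm> count = %.4f + %.5f * speed  (bin %.0f ms, p[b1] = %.3g)\n",
              x$coefficients["b0"], x$coefficients["b1"],
              x$bin_width * 1000, x$p_value))
  invisible(x)
}

#' Is a unit's spiking significantly speed-modulated?
#'
#' Two-sided t-test on the OLS slope of the speed model at level `alpha`.
#'
#' @param fit A [fit_speed_glm()] object.
#' @param alpha Significance level, default 0.05.
#' @return Logical flag.
#' @export
speed_modulation_significant <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "speed_glm"))
  is.finite(fit$p_value) && fit$p_value < alpha
}

#' Residualised linear rate map
#'
#' Replaces per-bin spike counts by the speed-model residuals: each time
#' bin's residual is assigned to the spatial bin the animal occupied, and
#' the per-spatial-bin residual sum is divided by occupancy. When the
#' fitted slope is zero this reduces to the ordinary raw map minus the
#' overall mean rate.
#'
#' @param fit A [fit_speed_glm()] object.
#' @param linpos [linearize_elm()] output.
#' @param maze The ELM [maze_spec()].
#' @param direction `"both"`, `"right"` or `"left"`.
#' @param bin_width Spatial bin (cm).
#' @param min_occupancy_s Visited-bin occupancy threshold.
#' @return Tibble `direction, bin, lo_cm, hi_cm, occupancy_s,
#'   resid_rate, visited`.
#' @export
residual_rate_map <- function(fit, linpos, maze, direction = "both",
                              bin_width = 2.5, min_occupancy_s = 0.1) {
  direction <- match.arg(direction, c("both", "right", "left"))
  edges <- linear_bin_edges(maze$track_length, bin_width)
  nb <- length(edges) - 1L
  tb <- fit$bins
  idx <- findInterval(tb$time_s, linpos$time_s, all.inside = TRUE)
  pos <- linpos$pos_cm[idx]
  dirs <- linpos$direction[idx]
  sel <- if (direction == "both") rep(TRUE, length(pos)) else dirs == direction
  bins <- bin_index(pos[sel], edges)
  occ <- vapply(seq_len(nb), function(b)
    sum(bins == b) * fit$bin_width, numeric(1))
  rsum <- vapply(seq_len(nb), function(b)
    sum(tb$resid[sel][bins == b]), numeric(1))
  visited <- occ >= min_occupancy_s
  tibble(direction = direction, bin = seq_len(nb),
         lo_cm = edges[-length(edges)], hi_cm = edges[-1],
         occupancy_s = occ,
         resid_rate = ifelse(occ > 0, rsum / occ, NA_real_),
         visited = visited)
}
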