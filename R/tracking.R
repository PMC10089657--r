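#' Instantaneous running speed from 2D tracking
#'
#' Speed is the Euclidean displacement between adjacent valid samples
#' divided by their actual time difference, so tracking dropouts are
#' bridged with the true elapsed time rather than the nominal frame
#' interval. The first valid sample inherits the speed of the second
#' (there is no displacement before it). An optional centred boxcar
#' smooths the speed series over valid samples.
#'
#' @param tracking Data frame with columns `time_s`, `x_cm`, `y_cm` and
#'   optionally a logical `valid` (default all valid).
#' @param smooth_window Boxcar width in samples (odd; 1 = no smoothing).
#' @return The input as a tibble with a `speed_cms` column (`NA` for
#'   invalid samples).
#' @export
compute_speed <- function(tracking, smooth_window = 1) {
  tracking <- as_tibble(tracking)
  if (!"valid" %in% names(tracking)) tracking$valid <- TRUE
  ok <- which(tracking$valid & is.finite(tracking$x_cm) & is.finite(tracking$y_cm))
  if (length(ok) < 2)
    abort("need at least 2 valid tracking samples to compute speed.",
          class = "elmaze_insufficient_data")
  t <- tracking$time_s[ok]; x <- tracking$x_cm[ok]; y <- tracking$y_cm[ok]
  dt <- diff(t)
  if (any(dt <= 0)) abort("tracking times must be strictly increasing.",
                          class = "elmaze_parameter_error")
  sp <- sqrt(diff(x)^2 + diff(y)^2) / dt
  sp <- c(sp[1], sp)
  if (smooth_window > 1) sp <- boxcar(sp, smooth_window)
  out <- rep(NA_real_, nrow(tracking))
  out[ok] <- sp
  tracking$speed_cms <- out
  tracking
}

# Centred boxcar with edge shrinkage (partial windows at the ends).
boxcar <- function(x, w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Linearise tracking on the elevated linear maze
#'
#' Projects each 2D position onto the track's long axis (the first
#' principal axis of the valid positions, oriented toward increasing x),
#' shifts so that the explored extent is centred on the track middle, and
#' clips to `[0, track_length]`. Running direction is assigned from the
#' sign of a smoothed position derivative with hysteresis: the direction
#' switches only after the animal has travelled `hysteresis_cm` back from
#' the extreme position reached, which suppresses jitter flips at the
#' turning points. Position 0 is the left (non-changing) reward end;
#' `"right"` means running toward the changing/open half.
#'
#' @param tracking Tracking data frame (`time_s`, `x_cm`, `y_cm`,
#'   optional `valid`).
#' @param maze An ELM [maze_spec()].
#' @param smooth_window Samples for the direction-smoothing boxcar.
#' @param hysteresis_cm Reversal distance before a direction switch.
#' @return Tibble `time_s, pos_cm, direction, speed_cms` (valid samples
#'   only), class `elm_linpos`.
#' @export
linearize_elm <- function(tracking, maze, smooth_window = 5, hysteresis_cm = 2.5) {
  stopifnot(inherits(maze, "maze_spec"))
  if (maze$kind != "ELM") abort("`maze` must be an ELM spec.", class = "elmaze_parameter_error")
  tracking <- compute_speed(tracking, smooth_window = 1)
  keep <- !is.na(tracking$speed_cms)
  tr <- tracking[keep, ]
  xy <- cbind(tr$x_cm, tr$y_cm)
  ctr <- colMeans(xy)
  xc <- sweep(xy, 2, ctr)
  sv <- svd(xc, nu = 0, nv = 1)
  if (sv$d[1] < 1e-9)
    abort("track axis undefined: tracking has zero spatial extent.",
          class = "elmaze_geometry_error")
  v <- sv$v[, 1]
  if (v[1] < 0) v <- -v                      # orient with increasing x
  proj <- as.numeric(xc %*% v)
  # centre the explored extent on the track middle
  pos <- proj - (min(proj) + max(proj)) / 2 + maze$middle
  pos <- pmin(pmax(pos, 0), maze$track_length)
  dir <- direction_with_hysteresis(boxcar(pos, smooth_window), hysteresis_cm)
  structure(tibble(time_s = tr$time_s, pos_cm = pos, direction = dir,
                   speed_cms = tr$speed_cms),
            class = c("elm_linpos", "tbl_df", "tbl", "data.frame"))
}

# Direction from a smoothed position series with hysteresis: keep the
# current direction until the position has retraced `hyst` cm from the
# running extreme.
direction_with_hysteresis <- function(pos, hyst) {
  n <- length(pos)
  dir <- character(n)
  cur <- if (n >= 2 && pos[min(which(abs(pos - pos[1]) > 1e-9), n)] < pos[1]) "left" else "right"
  extreme <- pos[1]
  for (i in seq_len(n)) {
    p <- pos[i]
    if (cur == "right") {
      if (p > extreme) extreme <- p
      if (extreme - p > hyst) { cur <- "left"; extreme <- p }
    } else {
      if (p < extreme) extreme <- p
      if (p - extreme > hyst) { cur <- "right"; extreme <- p }
    }
    dir[i] <- cur
  }
  dir
}

#' Segment linearised ELM running into directional trials
#'
#' A trial is the trajectory from where the animal left a reward zone and
#' crossed the middle of the track. End-to-end runs give one rewarded
#' directional trial. Runs that cross the middle but return to the origin
#' reward zone are counted as two unrewarded directional trials: an
#' outbound trial from the reward-zone exit to the turning point, and a
#' return trial from the turning point back. Runs that never cross the
#' middle give no trial. Excursions containing a tracking gap longer than
#' `max_gap_s` are discarded.
#'
#' @param linpos Output of [linearize_elm()].
#' @param maze The ELM [maze_spec()].
#' @param bin_width Bin width (cm) used for `furthest_bin` (default 2.5).
#' @param max_gap_s Gap length that invalidates an excursion.
#' @return Tibble `trial_id, start_s, end_s, direction, rewarded,
#'   furthest_pos_cm, furthest_bin`.
#' @export
segment_trials <- function(linpos, maze, bin_width = 2.5, max_gap_s = 0.5) {
  if (nrow(linpos) == 0) return(empty_trials())
  L <- maze$track_length; rz <- maze$reward_zone_length; mid <- maze$middle
  edges <- linear_bin_edges(L, bin_width)
  pos <- linpos$pos_cm; t <- linpos$time_s
  zone <- ifelse(pos <= rz, "L", ifelse(pos >= L - rz, "R", "track"))
  inz <- zone != "track"
  trials <- list()
  # indices where the animal sits in a reward zone
  zruns <- rle(zone)
  ends <- cumsum(zruns$lengths); starts <- ends - zruns$lengths + 1L
  zidx <- which(zruns$values != "track")
  if (length(zidx) < 1) return(empty_trials())
  for (k in seq_len(length(zidx) - 1L)) {
    a <- zidx[k]; b <- zidx[k + 1L]
    origin <- zruns$values[a]; dest <- zruns$values[b]
    i0 <- ends[a]             # last sample in origin zone (exit)
    i1 <- starts[b]           # first sample in destination zone (entry)
    if (i1 - i0 < 2) next
    seg <- i0:i1
    if (max(diff(t[seg])) > max_gap_s) next
    p <- pos[seg]
    if (origin == "L") { far <- max(p); crossed <- far >= mid } else { far <- min(p); crossed <- far <= mid }
    if (!crossed) next
    out_dir <- if (origin == "L") "right" else "left"
    far_bin <- bin_index(far, edges)
    if (dest != origin) {
      trials[[length(trials) + 1L]] <- tibble(
        start_s = t[i0], end_s = t[i1], direction = out_dir, rewarded = TRUE,
        furthest_pos_cm = if (origin == "L") max(p) else min(p),
        furthest_bin = far_bin)
    } else {
      turn <- seg[if (origin == "L") which.max(p) else which.min(p)]
      trials[[length(trials) + 1L]] <- tibble(
        start_s = t[i0], end_s = t[turn], direction = out_dir, rewarded = FALSE,
        furthest_pos_cm = far, furthest_bin = far_bin)
      trials[[length(trials) + 1L]] <- tibble(
        start_s = t[turn], end_s = t[i1],
        direction = if (out_dir == "right") "left" else "right",
        rewarded = FALSE, furthest_pos_cm = far, furthest_bin = far_bin)
    }
  }
  if (length(trials) == 0) return(empty_trials())
  out <- bind_rows(trials)
  out$trial_id <- seq_len(nrow(out))
  out[, c("trial_id", "start_s", "end_s", "direction", "rewarded",
          "furthest_pos_cm", "furthest_bin")]
}

empty_trials <- function() {
  tibble(trial_id = integer(), start_s = numeric(), end_s = numeric(),
         direction = character(), rewarded = logical(),
         furthest_pos_cm = numeric(), furthest_bin = integer())
}

#' Fraction of session time per maze zone
#'
#' For an ELM the zones are the non-changing arm, the centre band
#' (`centre_zone_width` total, centred on the middle) and the changing
#' arm, computed from linearised positions. For an EPM the zones are
#' closed arms, open arms and centre, computed from raw tracking and the
#' geometry. Each sample contributes its following inter-sample interval
#' (capped at 0.5 s across gaps; the last sample contributes the median
#' interval).
#'
#' @param data [linearize_elm()] output (ELM) or a tracking data frame
#'   (EPM).
#' @param maze A [maze_spec()] (ELM) or [epm_geometry()] (EPM).
#' @return Tibble `zone, time_s, fraction`; fractions sum to 1.
#' @export
zone_occupancy <- function(data, maze) {
  if (inherits(maze, "maze_spec") && maze$kind == "ELM") {
    zones <- elm_zone(data$pos_cm, maze)
    t <- data$time_s
    levels_ <- c("non_changing_arm", "centre", "changing_arm")
  } else if (inherits(maze, "epm_geometry")) {
    region <- epm_region(data$x_cm, data$y_cm, maze)
    keep <- !is.na(region)
    data <- data[keep, ]; region <- region[keep]
    zones <- ifelse(region %in% c("closed1", "closed2"), "closed_arms",
                    ifelse(region %in% c("open1", "open2"), "open_arms", "centre"))
    t <- data$time_s
    levels_ <- c("closed_arms", "centre", "open_arms")
  } else {
    abort("`maze` must be a maze_spec (ELM) or epm_geometry.",
          class = "elmaze_parameter_error")
  }
  if (length(t) == 0) abort("no valid samples: zone fractions undefined.",
                            class = "elmaze_insufficient_data")
  dt <- diff(t)
  dt <- pmin(dt, 0.5)
  dt <- c(dt, if (length(dt)) median(dt) else 1)
  tot <- sum(dt)
  tab <- tapply(dt, factor(zones, levels = levels_), sum, default = 0)
  tibble(zone = levels_, time_s = as.numeric(tab), fraction = as.numeric(tab) / tot)
}

#' Extract linearised elevated-plus-maze trajectories
#'
#' A trajectory runs from the furthest point reached on one (closed) arm
#' to the furthest point reached on the next visited arm, through the
#' centre. Each arm sample gets a linear coordinate by projecting its
#' position onto the arm's directional vector (`(P . D)/||D||`); centre
#' samples are kept unprojected for later time-binning. Samples falling
#' in neither an arm nor the centre are dropped (and counted).
#'
#' @param tracking Tracking data frame (`time_s`, `x_cm`, `y_cm`).
#' @param geom An [epm_geometry()].
#' @param from_closed_only Keep only trajectories that start on a closed
#'   arm (the six ordered closed-to-other-arm types); default `TRUE`.
#' @return Tibble with one row per trajectory: `type, from, to, start_s,
#'   end_s, n_dropped` and a list-column `data` of per-sample tibbles
#'   (`time_s, x_cm, y_cm, region, segment, lin_cm`).
#' @export
linearize_epm_trajectory <- function(tracking, geom, from_closed_only = TRUE) {
  stopifnot(inherits(geom, "epm_geometry"))
  tracking <- as_tibble(tracking)
  region <- epm_region(tracking$x_cm, tracking$y_cm, geom)
  n_dropped <- sum(is.na(region))
  keep <- !is.na(region)
  tr <- tracking[keep, ]; region <- region[keep]
  if (nrow(tr) == 0) return(empty_epm_trajectories())
  r <- rle(region)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  armruns <- which(r$values %in% names(geom$arms))
  out <- list()
  if (length(armruns) >= 2) {
    for (k in seq_len(length(armruns) - 1L)) {
      a <- armruns[k]; b <- armruns[k + 1L]
      from <- r$values[a]; to <- r$values[b]
      if (from == to) next
      if (from_closed_only && !from %in% c("closed1", "closed2")) next
      ia <- starts[a]:ends[a]; ib <- starts[b]:ends[b]
      proj_a <- project_onto_arm(tr$x_cm[ia], tr$y_cm[ia], geom$arms[[from]])
      proj_b <- project_onto_arm(tr$x_cm[ib], tr$y_cm[ib], geom$arms[[to]])
      i0 <- ia[which.max(proj_a)]   # furthest point on origin arm
      i1 <- ib[which.max(proj_b)]   # furthest point on destination arm
      idx <- i0:i1
      seg_region <- region[idx]
      segment <- ifelse(seg_region == from, "start_arm",
                        ifelse(seg_region == "centre", "centre",
                               ifelse(seg_region == to, "end_arm", NA_character_)))
      dat <- tibble(time_s = tr$time_s[idx], x_cm = tr$x_cm[idx],
                    y_cm = tr$y_cm[idx], region = seg_region, segment = segment)
      dat <- dat[!is.na(dat$segment), ]
      dat$lin_cm <- NA_real_
      sa <- dat$segment == "start_arm"
      dat$lin_cm[sa] <- project_onto_arm(dat$x_cm[sa], dat$y_cm[sa], geom$arms[[from]])
      ea <- dat$segment == "end_arm"
      dat$lin_cm[ea] <- project_onto_arm(dat$x_cm[ea], dat$y_cm[ea], geom$arms[[to]])
      out[[length(out) + 1L]] <- tibble(
        type = paste0(from, "_to_", to), from = from, to = to,
        start_s = dat$time_s[1], end_s = dat$time_s[nrow(dat)],
        n_dropped = n_dropped, data = list(dat))
    }
  }
  if (length(out) == 0) return(empty_epm_trajectories())
  bind_rows(out)
}

empty_epm_trajectories <- function() {
  tibble(type = character(), from = character(), to = character(),
         start_s = numeric(), end_s = numeric(), n_dropped = integer(),
         data = list())
}
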