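# Seeded synthetic sessions: shuttling trajectories on the elevated
# linear maze, inhomogeneous-Poisson place cells with direction-dependent
# Gaussian tuning, additive speed modulation, ripple-embedded LFP, and
# waveform summaries spanning both cell classes. The generator writes a
# full ground-truth record so every downstream stage can be scored
# without re-deriving the truth.

#' Behavioural simulation parameters
#'
#' Shuttling is bout-based: the animal runs end to end at a per-leg speed
#' drawn from `N(mean_speed, speed_sd)`, pausing `reward_dwell_s` at the
#' reward ends. In the CO configuration it additionally dwells
#' `hesitation_dwell_s` at the closed-side boundary of the centre band
#' before heading into the open half, and each open-half entry turns back
#' before the far end with probability `retreat_prob` (turning point
#' drawn around the middle of the open half with SD `retreat_depth_sd`).
#'
#' @param n_shuttles Completed end-to-end runs per direction (0 gives a
#'   stationary session at the left reward zone).
#' @param frame_rate Tracking rate (Hz), default 50.
#' @param mean_speed,speed_sd Per-leg running speed distribution (cm/s).
#' @param reward_dwell_s Dwell at each reward end (s).
#' @param hesitation_dwell_s Extra centre-boundary dwell before open-half
#'   entries (s; CO only).
#' @param retreat_prob Probability an open-half entry retreats (CO only).
#' @param retreat_depth_sd SD of the retreat turning point (cm).
#' @param seed Integer seed.
#' @return A `behaviour_params` list.
#' @export
behaviour_params <- function(n_shuttles = 12, frame_rate = 50,
                             mean_speed = 25, speed_sd = 5,
                             reward_dwell_s = 1.5, hesitation_dwell_s = 2,
                             retreat_prob = 0, retreat_depth_sd = 10,
                             seed = 1) {
  if (frame_rate <= 0) abort("frame_rate must be positive.",
                             class = "elmaze_parameter_error")
  if (n_shuttles < 0) abort("n_shuttles must be non-negative.",
                            class = "elmaze_parameter_error")
  if (retreat_prob < 0 || retreat_prob > 1)
    abort("retreat_prob must lie in [0, 1].", class = "elmaze_parameter_error")
  if (mean_speed <= 0 || speed_sd < 0 || reward_dwell_s < 0 ||
      hesitation_dwell_s < 0 || retreat_depth_sd < 0)
    abort("rates and durations must be non-negative.",
          class = "elmaze_parameter_error")
  structure(as.list(environment()), class = "behaviour_params")
}

#' Simulate a shuttling trajectory on the elevated linear maze
#'
#' Generates frame-by-frame positions for `n_shuttles` completed runs in
#' each direction, with the CO-specific hesitation and retreat behaviour
#' of [behaviour_params()]. Retreat excursions (enter the open half, turn
#' back) are extra runs on top of the completed count. Deterministic for
#' a given seed.
#'
#' @param maze An ELM [maze_spec()].
#' @param params A [behaviour_params()] list.
#' @return Tracking tibble `time_s, x_cm, y_cm, valid` with attributes
#'   `frames` (per-frame `heading`, `approach_id`, `upcoming_retreat`)
#'   and `open_entries` (per open-half entry: `entry_id, t_entry,
#'   retreat`).
#' @export
simulate_trajectory <- function(maze, params) {
  stopifnot(inherits(maze, "maze_spec"), inherits(params, "behaviour_params"))
  if (maze$kind != "ELM")
    abort("trajectory generator supports the ELM only.",
          class = "elmaze_parameter_error")
  fps <- params$frame_rate; dt <- 1 / fps
  L <- maze$track_length; rz <- maze$reward_zone_length
  p_left <- rz / 2; p_right <- L - rz / 2
  hp <- maze$middle - maze$centre_zone_width / 2   # hesitation point
  is_co <- identical(maze$configuration, "CO")
  with_seed(params$seed, {
    pos <- list(); heading <- list(); appr <- list(); retr <- list()
    entries <- list()
    emit <- function(p, h, a = NA_integer_, r = NA) {
      pos[[length(pos) + 1L]] <<- p
      heading[[length(heading) + 1L]] <<- rep(h, length(p))
      appr[[length(appr) + 1L]] <<- rep(a, length(p))
      retr[[length(retr) + 1L]] <<- rep(r, length(p))
    }
    leg <- function(p0, p1) {
      v <- max(rnorm(1, params$mean_speed, params$speed_sd), 5)
      npts <- max(1L, round(abs(p1 - p0) / v * fps))
      seq(p0, p1, length.out = npts + 1L)[-1L]
    }
    dwell <- function(p, secs) rep(p, max(1L, round(secs * fps)))
    emit(dwell(p_left, params$reward_dwell_s), "dwell")
    entry_id <- 0L
    if (params$n_shuttles > 0) for (sh in seq_len(params$n_shuttles)) {
      done <- FALSE
      while (!done) {                      # rightward (toward changing half)
        entry_id <- entry_id + 1L
        retreat <- is_co && runif(1) < params$retreat_prob
        lg <- leg(p_left, hp)
        before <- lg[lg < hp - 1e-9]
        emit(c(before, hp), "right", a = entry_id, r = retreat)
        if (is_co && params$hesitation_dwell_s > 0)
          emit(dwell(hp, params$hesitation_dwell_s), "dwell",
               a = entry_id, r = retreat)
        if (retreat) {
          # hesitant entries venture only a short way past the boundary
          depth <- rnorm(1, (L - maze$middle) / 4, params$retreat_depth_sd)
          tp <- min(max(maze$middle + abs(depth), maze$middle + 2),
                    L - rz - 1)
          emit(leg(hp, tp), "right", a = entry_id, r = retreat)
          emit(leg(tp, p_left), "left")
          emit(dwell(p_left, params$reward_dwell_s / 2), "dwell")
        } else {
          emit(leg(hp, p_right), "right", a = entry_id, r = retreat)
          emit(dwell(p_right, params$reward_dwell_s), "dwell")
          done <- TRUE
        }
        entries[[entry_id]] <- tibble(entry_id = entry_id, retreat = retreat)
      }
      emit(leg(p_right, p_left), "left")   # leftward run always completes
      emit(dwell(p_left, params$reward_dwell_s), "dwell")
    }
    x <- unlist(pos)
    n <- length(x)
    y <- pmin(pmax(rnorm(n, 0, 0.3), -maze$track_width / 2),
              maze$track_width / 2)
    tracking <- tibble(time_s = (seq_len(n) - 1L) * dt, x_cm = x, y_cm = y,
                       valid = TRUE)
    frames <- tibble(heading = unlist(heading),
                     approach_id = unlist(appr),
                     upcoming_retreat = unlist(retr))
    ent <- if (length(entries)) bind_rows(entries) else
      tibble(entry_id = integer(), retreat = logical())
    if (nrow(ent)) {
      ent$t_entry <- vapply(ent$entry_id, function(id)
        tracking$time_s[match(id, frames$approach_id)], numeric(1))
    } else ent$t_entry <- numeric(0)
    attr(tracking, "frames") <- frames
    attr(tracking, "open_entries") <- ent[, c("entry_id", "t_entry", "retreat")]
    tracking
  })
}

#' Place-cell tuning parameters
#'
#' A neuron's instantaneous rate is
#' `baseline + peak * exp(-(pos - centre_dir)^2 / (2 width^2)) +
#' speed_gain * speed(t)`, with a separate field centre per running
#' direction; spikes are drawn as an inhomogeneous Poisson process.
#'
#' @param field_centre_right,field_centre_left Field centres (cm) for the
#'   two running directions.
#' @param field_width Gaussian SD of the field (cm).
#' @param peak_rate,baseline_rate In-field peak and out-of-field rates
#'   (Hz).
#' @param speed_gain Additive rate gain (Hz per cm/s).
#' @param seed Integer seed.
#' @return A `neuron_params` list.
#' @export
neuron_params <- function(field_centre_right = 60, field_centre_left = 60,
                          field_width = 8, peak_rate = 8,
                          baseline_rate = 0.5, speed_gain = 0, seed = 1) {
  if (peak_rate < 0 || baseline_rate < 0 || field_width <= 0 || speed_gain < 0)
    abort("rates must be non-negative and field_width positive.",
          class = "elmaze_parameter_error")
  structure(as.list(environment()), class = "neuron_params")
}

#' Simulate a spike train from tracking and tuning
#'
#' Draws an inhomogeneous Poisson spike train: per-frame counts are
#' Poisson with mean `rate(t) / frame_rate`, and spike times are placed
#' uniformly within their frame. The rate is the [neuron_params()] model
#' evaluated on the linear position (the tracking x-coordinate, clipped
#' to the track), the running direction, and the instantaneous speed.
#'
#' @param tuning A [neuron_params()] list.
#' @param tracking Tracking tibble (from [simulate_trajectory()]).
#' @param maze The ELM [maze_spec()].
#' @param extra_rate Optional per-frame additive rate (Hz), e.g. a
#'   planted pre-entry decoding signal.
#' @param seed Overrides `tuning$seed` when given.
#' @return Sorted numeric vector of spike times (s).
#' @export
simulate_spikes <- function(tuning, tracking, maze, extra_rate = NULL,
                            seed = NULL) {
  stopifnot(inherits(tuning, "neuron_params"))
  if (nrow(tracking) == 0) abort("empty tracking.",
                                 class = "elmaze_insufficient_data")
  pos <- pmin(pmax(tracking$x_cm, 0), maze$track_length)
  dpos <- c(0, diff(pos))
  dir_sign <- sign(dpos)
  for (i in seq_along(dir_sign))                   # carry direction over pauses
    if (dir_sign[i] == 0 && i > 1) dir_sign[i] <- dir_sign[i - 1]
  centre <- ifelse(dir_sign >= 0, tuning$field_centre_right,
                   tuning$field_centre_left)
  dt <- c(diff(tracking$time_s), median(diff(tracking$time_s)))
  if (nrow(tracking) == 1) dt <- 0.02
  speed <- abs(dpos) / ifelse(dt > 0, dt, 1)
  rate <- tuning$baseline_rate +
    tuning$peak_rate * exp(-(pos - centre)^2 / (2 * tuning$field_width^2)) +
    tuning$speed_gain * speed
  if (!is.null(extra_rate)) rate <- rate + extra_rate
  if (any(rate < 0)) abort("negative instantaneous rate.",
                           class = "elmaze_internal_error")
  with_seed(if (is.null(seed)) tuning$seed else seed, {
    counts <- rpois(length(rate), rate * dt)
    idx <- rep.int(seq_along(counts), counts)
    if (length(idx) == 0) numeric(0)
    else sort(tracking$time_s[idx] + runif(length(idx)) * dt[idx])
  })
}

#' Simulate an LFP trace with embedded sharp-wave ripples
#'
#' Gaussian background noise plus Hanning-enveloped oscillatory bursts at
#' `swr_freq` (which must lie in the 130-230 Hz ripple band). Burst peak
#' amplitude is `swr_amplitude_sd_units` background SDs. Burst supports
#' are returned as the ground-truth event intervals; bursts are placed
#' uniformly with non-overlapping supports.
#'
#' @param fs Sampling rate (Hz).
#' @param duration_s Trace duration (s).
#' @param noise_sd Background SD (a.u.).
#' @param swr_rate Events per second (0 for none).
#' @param swr_freq Ripple frequency (Hz), in `[130, 230]`.
#' @param swr_duration_ms Burst duration (ms).
#' @param swr_amplitude_sd_units Peak amplitude in background SDs.
#' @param seed Integer seed.
#' @param n_events Fix the event count instead of drawing it Poisson.
#' @return List `trace` (numeric), `fs`, `t0`, `events` (tibble
#'   `start_s, end_s`).
#' @export
simulate_lfp <- function(fs = 1250, duration_s = 60, noise_sd = 1,
                         swr_rate = 0.1, swr_freq = 150,
                         swr_duration_ms = 60, swr_amplitude_sd_units = 8,
                         seed = 1, n_events = NULL) {
  if (swr_freq < 130 || swr_freq > 230)
    abort("swr_freq must lie in the 130-230 Hz ripple band.",
          class = "elmaze_parameter_error")
  if (swr_amplitude_sd_units <= 0 || swr_rate < 0 || duration_s <= 0)
    abort("invalid LFP parameters.", class = "elmaze_parameter_error")
  n <- round(fs * duration_s)
  m <- max(8L, round(fs * swr_duration_ms / 1000))
  with_seed(seed, {
    trace <- rnorm(n, 0, noise_sd)
    k <- if (!is.null(n_events)) n_events else rpois(1, swr_rate * duration_s)
    starts <- integer(0)
    tries <- 0
    while (length(starts) < k && tries < 200 * max(k, 1)) {
      cand <- sample.int(max(n - m, 1), 1)
      tries <- tries + 1
      if (all(abs(cand - starts) > 3 * m)) starts <- c(starts, cand)
    }
    starts <- sort(starts)
    env <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
    events <- list()
    for (s0 in starts) {
      idx <- s0:(s0 + m - 1L)
      phase <- runif(1, 0, 2 * pi)
      burst <- swr_amplitude_sd_units * noise_sd * env *
        sin(2 * pi * swr_freq * (idx - s0) / fs + phase)
      trace[idx] <- trace[idx] + burst
      events[[length(events) + 1L]] <-
        tibble(start_s = (s0 - 1) / fs, end_s = (s0 + m - 2) / fs)
    }
    ev <- if (length(events)) bind_rows(events) else
      tibble(start_s = numeric(), end_s = numeric())
    list(trace = trace, fs = fs, t0 = 0, events = ev)
  })
}

#' Population-level tuning parameters
#'
#' Field centres in the baseline (CC) configuration are uniform over the
#' track interior; the two directional centres coincide with probability
#' `direction_similarity`. In the CO configuration a fraction
#' `remap_to_open_prob` of neurons relocate their field into the open
#' half, and the directional centres are (re-)homogenised with
#' probability `co_direction_similarity` (defaults to
#' `direction_similarity`). A fraction `interneuron_frac` of units carry
#' interneuron-like waveform statistics, the rest pyramidal-like.
#'
#' @param n_neurons Number of units.
#' @param field_width,peak_rate,baseline_rate,speed_gain As
#'   [neuron_params()] (shared by all units).
#' @param direction_similarity Probability the two directional fields
#'   coincide in CC, in `[0, 1]`.
#' @param remap_to_open_prob Probability a neuron's field moves into the
#'   open half in CO.
#' @param co_direction_similarity Homogenisation probability in CO.
#' @param interneuron_frac Fraction of interneuron-like waveforms.
#' @return A `population_params` list.
#' @export
population_params <- function(n_neurons = 30, field_width = 8,
                              peak_rate = 8, baseline_rate = 0.5,
                              speed_gain = 0, direction_similarity = 0.5,
                              remap_to_open_prob = 0.3,
                              co_direction_similarity = NULL,
                              interneuron_frac = 0.15) {
  if (direction_similarity < 0 || direction_similarity > 1 ||
      remap_to_open_prob < 0 || remap_to_open_prob > 1)
    abort("probabilities must lie in [0, 1].", class = "elmaze_parameter_error")
  if (is.null(co_direction_similarity))
    co_direction_similarity <- direction_similarity
  structure(as.list(environment()), class = "population_params")
}

#' Decoding-signal parameters
#'
#' Plants a pre-entry exploration signal: during the closed-half approach
#' of each open-half entry, the first `n_informative` units add
#' `rate_distal_hz` (entries that will complete) or `rate_proximal_hz`
#' (entries that will retreat) to their instantaneous rate. With
#' `n_informative = 0` the session carries no decodable signal.
#'
#' @param n_informative Number of informative units.
#' @param rate_distal_hz,rate_proximal_hz Added approach rates (Hz).
#' @return A `decoding_params` list.
#' @export
decoding_params <- function(n_informative = 0, rate_distal_hz = 0,
                            rate_proximal_hz = 0) {
  structure(as.list(environment()), class = "decoding_params")
}

#' Simulate a complete recording session
#'
#' Composes trajectory, spikes, LFP and waveform statistics across
#' configuration epochs (default CC then CO) into one session with a full
#' ground-truth record: true field centres per epoch and direction, true
#' remap-to-open flags, true homogenisation flags, open-entry/retreat
#' log, true ripple intervals and the planted decoding signal.
#' Byte-identical for a given seed.
#'
#' @param behaviour A [behaviour_params()] list (its `seed` is ignored;
#'   epoch seeds derive from `seed`).
#' @param neurons A [population_params()] list.
#' @param lfp_params Named list overriding [simulate_lfp()] defaults
#'   (`fs`, `noise_sd`, `swr_rate`, ...), or `NULL` to skip the LFP.
#' @param decoding A [decoding_params()] list.
#' @param epochs Character vector of ELM configurations in presentation
#'   order.
#' @param maze Base [maze_spec()] geometry.
#' @param seed Integer master seed.
#' @return A list of class `elm_session`: `tracking`, `spikes`
#'   (`unit_id, time_s`), `units` (waveform stats), `lfp`, `epochs`
#'   (tibble `configuration, start_s, end_s`), `maze`, `truth`.
#' @export
simulate_session <- function(behaviour = behaviour_params(),
                             neurons = population_params(),
                             lfp_params = list(),
                             decoding = decoding_params(),
                             epochs = c("CC", "CO"),
                             maze = maze_spec("ELM", "CC"),
                             seed = 1) {
  stopifnot(inherits(behaviour, "behaviour_params"),
            inherits(neurons, "population_params"))
  L <- maze$track_length; mid <- maze$middle
  np <- neurons$n_neurons
  # --- per-neuron truth -----------------------------------------------
  truth_neurons <- with_seed(child_seed(seed, "session"), {
    cc_r <- runif(np, 10, L - 10)
    same <- runif(np) < neurons$direction_similarity
    cc_l <- ifelse(same, cc_r, runif(np, 10, L - 10))
    remap <- runif(np) < neurons$remap_to_open_prob
    open_c <- runif(np, mid + 5, L - 5)
    homog <- runif(np) < neurons$co_direction_similarity
    co_r <- ifelse(remap, open_c, cc_r)
    co_l <- ifelse(homog, co_r, ifelse(remap, open_c, cc_l))
    is_int <- runif(np) < neurons$interneuron_frac
    tibble(unit_id = seq_len(np),
           cc_centre_right = cc_r, cc_centre_left = cc_l,
           co_centre_right = co_r, co_centre_left = co_l,
           remap_to_open = remap, homogenised = homog,
           interneuron_like = is_int,
           trough_to_peak_ms = ifelse(is_int, runif(np, 0.08, 0.28),
                                      runif(np, 0.35, 0.9)),
           waveform_rate_hz = ifelse(is_int, runif(np, 12, 30),
                                     runif(np, 0.5, 8)))
  })
  informative <- if (decoding$n_informative > 0) {
    pyr <- which(!truth_neurons$interneuron_like)
    head(pyr, decoding$n_informative)
  } else integer(0)
  # --- epochs ----------------------------------------------------------
  tracking_all <- list(); spikes_all <- list(); epoch_rows <- list()
  behaviour_truth <- list()
  t_offset <- 0
  for (e in seq_along(epochs)) {
    cfg <- epochs[e]
    maze_e <- maze
    maze_e$configuration <- cfg
    beh_e <- behaviour; beh_e$seed <- child_seed(seed, "trajectory", e)
    trk <- simulate_trajectory(maze_e, beh_e)
    frames <- attr(trk, "frames")
    entries <- attr(trk, "open_entries")
    centres <- if (cfg == "CO") {
      list(r = truth_neurons$co_centre_right, l = truth_neurons$co_centre_left)
    } else {
      list(r = truth_neurons$cc_centre_right, l = truth_neurons$cc_centre_left)
    }
    # planted pre-entry signal (approach frames in the closed half)
    extra_base <- rep(0, nrow(trk))
    approach <- !is.na(frames$approach_id) &
      pmin(pmax(trk$x_cm, 0), L) < mid - 2.5
    extra_sig <- ifelse(approach & frames$upcoming_retreat %in% TRUE,
                        decoding$rate_proximal_hz,
                        ifelse(approach, decoding$rate_distal_hz, 0))
    for (u in seq_len(np)) {
      tun <- neuron_params(field_centre_right = centres$r[u],
                           field_centre_left = centres$l[u],
                           field_width = neurons$field_width,
                           peak_rate = neurons$peak_rate,
                           baseline_rate = neurons$baseline_rate,
                           speed_gain = neurons$speed_gain)
      extra <- if (u %in% informative && cfg == "CO") extra_sig else extra_base
      st <- simulate_spikes(tun, trk, maze_e, extra_rate = extra,
                            seed = child_seed(seed, "spikes", u * 1000 + e))
      if (length(st))
        spikes_all[[length(spikes_all) + 1L]] <-
          tibble(unit_id = u, time_s = st + t_offset)
    }
    trk$time_s <- trk$time_s + t_offset
    epoch_rows[[e]] <- tibble(configuration = cfg, start_s = t_offset,
                              end_s = max(trk$time_s))
    if (nrow(entries)) entries$t_entry <- entries$t_entry + t_offset
    behaviour_truth[[e]] <- list(configuration = cfg, open_entries = entries)
    tracking_all[[e]] <- trk
    t_offset <- max(trk$time_s) + 1 / behaviour$frame_rate
  }
  tracking <- bind_rows(lapply(tracking_all, function(x) {
    attributes(x)[c("frames", "open_entries")] <- NULL; x
  }))
  spikes <- if (length(spikes_all)) arrange(bind_rows(spikes_all),
                                            .data$unit_id, .data$time_s)
  else tibble(unit_id = integer(), time_s = numeric())
  # --- LFP -------------------------------------------------------------
  lfp <- NULL
  if (!is.null(lfp_params)) {
    la <- utils::modifyList(
      list(fs = 1250, duration_s = t_offset, noise_sd = 1, swr_rate = 0.05,
           swr_freq = 150, swr_duration_ms = 60, swr_amplitude_sd_units = 8,
           seed = child_seed(seed, "lfp")),
      lfp_params)
    lfp <- do.call(simulate_lfp, la)
  }
  units <- classify_unit(tibble(
    unit_id = truth_neurons$unit_id,
    trough_to_peak_ms = truth_neurons$trough_to_peak_ms,
    mean_rate_hz = truth_neurons$waveform_rate_hz))
  structure(list(
    tracking = tracking, spikes = spikes, units = units, lfp = lfp,
    epochs = bind_rows(epoch_rows), maze = maze,
    truth = list(neurons = truth_neurons, behaviour = behaviour_truth,
                 swr_events = if (!is.null(lfp)) lfp$events else NULL,
                 informative_units = informative,
                 params = list(behaviour = unclass(behaviour),
                               neurons = unclass(neurons),
                               decoding = unclass(decoding), seed = seed))
  ), class = "elm_session")
}

#' @export
print.elm_session <- function(x, ...) {
  cat(sprintf("<elm_session> %d epochs (%s), %.0f s, %d units, %d spikes%s\n",
              nrow(x$epochs), paste(x$epochs$configuration, collapse = ", "),
              max(x$tracking$time_s), nrow(x$units), nrow(x$spikes),
              if (is.null(x$lfp)) "" else sprintf(", LFP %.0f Hz", x$lfp$fs)))
  invisible(x)
}
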