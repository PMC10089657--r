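# Session-level orchestration: configuration, per-epoch staging
# (tracking -> maps -> metrics -> unit processing -> decoding), the
# cross-epoch comparisons, and plain-text session/report I/O.

#' Analysis configuration
#'
#' Collects every tunable of the per-session pipeline with its default.
#'
#' @param bin_width Linear spatial bin (cm).
#' @param smooth_sd_bins Gaussian smoothing SD in bins.
#' @param min_occupancy_s Visited-bin occupancy threshold (s).
#' @param min_spikes Minimum in-epoch spikes for a unit's spatial metrics.
#' @param exclude_swr Remove ripple-associated spikes before mapping.
#' @param speed_glm Fit the per-unit speed model.
#' @param glm_bin_s Speed-model time bin (s).
#' @param decode Run the proximal/distal decoding stage on the CO epoch.
#' @param n_shuffles Label permutations for the decoding null.
#' @param n_bootstrap Peak reassignments for the density null.
#' @param alpha Significance level used throughout.
#' @param threshold_rule Proximal/distal threshold reading
#'   (see [label_trials()]).
#' @param seed Seed for all pipeline randomness.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(bin_width = 2.5, smooth_sd_bins = 1,
                            min_occupancy_s = 0.1, min_spikes = 15,
                            exclude_swr = TRUE, speed_glm = TRUE,
                            glm_bin_s = 0.02, decode = TRUE,
                            n_shuffles = 1000, n_bootstrap = 1000,
                            alpha = 0.05, threshold_rule = "midpoint",
                            seed = 1) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full single-session analysis
#'
#' Per configuration epoch: linearises tracking, segments trials,
#' computes zone occupancy, builds per-unit directional rate maps,
#' spatial statistics, peak locations and place-field similarity, and
#' fits the per-unit speed model. Across epochs it tests peak-location
#' proportions (even-chance and CC-referenced chi-square) and compares
#' PFS distributions (rank-sum). If an LFP is present, ripples are
#' detected and (optionally) ripple spikes excised before mapping; if a
#' CO epoch with enough units and trials is present, the
#' proximal/distal decoding stage runs. Missing inputs skip their stage
#' with a logged reason. Output is fully determined by the session and
#' `config$seed`.
#'
#' @param session An `elm_session` (from [simulate_session()] or
#'   [read_session()]).
#' @param config An [analysis_config()].
#' @return A list of class `elm_report`.
#' @export
run_session_analysis <- function(session, config = analysis_config()) {
  stopifnot(inherits(session, "elm_session"))
  cfg <- config
  skipped <- list()
  # --- SWR stage ------------------------------------------------------
  swr <- NULL
  spikes <- session$spikes
  if (!is.null(session$lfp)) {
    swr <- detect_swr(session$lfp$trace, session$lfp$fs, t0 = session$lfp$t0)
    if (cfg$exclude_swr && nrow(swr)) {
      spikes <- exclude_swr_spikes(spikes, swr)
    }
  } else {
    skipped$swr <- "no LFP in session"
  }
  # --- per-epoch stages -----------------------------------------------
  epochs <- session$epochs
  unit_ids <- sort(unique(session$units$unit_id))
  behaviour <- list(); metrics <- list(); pfs_rows <- list()
  glm_rows <- list(); linpos_by_epoch <- list(); trials_by_epoch <- list()
  for (e in seq_len(nrow(epochs))) {
    cfg_name <- epochs$configuration[e]
    maze_e <- session$maze; maze_e$configuration <- cfg_name
    sel <- session$tracking$time_s >= epochs$start_s[e] &
      session$tracking$time_s <= epochs$end_s[e]
    trk <- session$tracking[sel, ]
    linpos <- linearize_elm(trk, maze_e)
    trials <- segment_trials(linpos, maze_e, bin_width = cfg$bin_width)
    linpos_by_epoch[[cfg_name]] <- linpos
    trials_by_epoch[[cfg_name]] <- trials
    zo <- zone_occupancy(linpos, maze_e)
    zo$epoch <- cfg_name
    behaviour[[e]] <- zo
    for (u in unit_ids) {
      st <- spikes$time_s[spikes$unit_id == u]
      st <- st[st >= epochs$start_s[e] & st <= epochs$end_s[e]]
      if (length(st) < cfg$min_spikes) next
      res <- tryCatch({
        mp_both <- linear_rate_map(linpos, st, maze_e, direction = "both",
                                   bin_width = cfg$bin_width,
                                   smooth_sd_bins = cfg$smooth_sd_bins,
                                   min_occupancy_s = cfg$min_occupancy_s)
        mp_r <- linear_rate_map(linpos, st, maze_e, direction = "right",
                                bin_width = cfg$bin_width,
                                smooth_sd_bins = cfg$smooth_sd_bins,
                                min_occupancy_s = cfg$min_occupancy_s)
        mp_l <- linear_rate_map(linpos, st, maze_e, direction = "left",
                                bin_width = cfg$bin_width,
                                smooth_sd_bins = cfg$smooth_sd_bins,
                                min_occupancy_s = cfg$min_occupancy_s)
        ss <- spatial_stats(mp_both)
        pk <- peak_bin(mp_both)
        pk_cm <- (mp_both$lo_cm[pk] + mp_both$hi_cm[pk]) / 2
        metrics[[length(metrics) + 1L]] <- tibble(
          unit_id = u, epoch = cfg_name, n_spikes = length(st),
          mean_rate_hz = ss$mean_rate_hz, si_bits = ss$si_bits,
          sparsity = ss$sparsity, coherence_z = ss$coherence_z,
          peak_bin = pk, peak_cm = pk_cm,
          peak_half = if (pk_cm >= maze_e$middle) "changing" else "non_changing")
        pf <- pfs(z_transform(mp_r), z_transform(mp_l))
        pfs_rows[[length(pfs_rows) + 1L]] <- tibble(
          unit_id = u, epoch = cfg_name, pfs = pf$pfs,
          n_bins_used = pf$n_bins_used)
        TRUE
      }, elmaze_insufficient_bins = function(c) FALSE,
         elmaze_empty_map = function(c) FALSE)
      if (cfg$speed_glm && length(st) >= 2) {
        fit <- tryCatch(
          fit_speed_glm(st, linpos, bin_width = cfg$glm_bin_s),
          error = function(c) NULL)
        if (!is.null(fit))
          glm_rows[[length(glm_rows) + 1L]] <- tibble(
            unit_id = u, epoch = cfg_name,
            b0 = fit$coefficients["b0"], b1 = fit$coefficients["b1"],
            p_value = fit$p_value,
            significant = speed_modulation_significant(fit, cfg$alpha))
      }
    }
  }
  metrics <- if (length(metrics)) bind_rows(metrics) else NULL
  pfs_tbl <- if (length(pfs_rows)) bind_rows(pfs_rows) else NULL
  glm_tbl <- if (length(glm_rows)) bind_rows(glm_rows) else NULL
  # --- cross-epoch comparisons ----------------------------------------
  proportions <- NULL; pfs_comparison <- NULL
  if (!is.null(metrics)) {
    counts_by_epoch <- lapply(split(metrics, metrics$epoch), function(m)
      c(changing = sum(m$peak_half == "changing"),
        non_changing = sum(m$peak_half == "non_changing")))
    prop <- list()
    for (ep in names(counts_by_epoch)) {
      pt <- proportion_test(counts_by_epoch[[ep]], mode = "even")
      pt$epoch <- ep; pt$reference <- NA_character_
      prop[[length(prop) + 1L]] <- pt
    }
    ref_ep <- intersect(c("CC", "CC2"), names(counts_by_epoch))[1]
    for (ep in setdiff(names(counts_by_epoch), ref_ep)) {
      if (!is.na(ref_ep) && all(counts_by_epoch[[ref_ep]] > 0)) {
        pt <- proportion_test(counts_by_epoch[[ep]], mode = "reference",
                              reference = counts_by_epoch[[ref_ep]])
        pt$epoch <- ep; pt$reference <- ref_ep
        prop[[length(prop) + 1L]] <- pt
      }
    }
    proportions <- bind_rows(prop)
  } else skipped$proportions <- "no unit passed the spike threshold"
  if (!is.null(pfs_tbl) && length(unique(pfs_tbl$epoch)) >= 2) {
    eps <- unique(pfs_tbl$epoch)
    cmp <- list()
    for (i in seq_len(length(eps) - 1)) for (j in (i + 1):length(eps)) {
      a <- pfs_tbl$pfs[pfs_tbl$epoch == eps[i]]
      b <- pfs_tbl$pfs[pfs_tbl$epoch == eps[j]]
      if (length(a) >= 2 && length(b) >= 2) {
        pc <- suppressWarnings(paired_compare(a, b, "wilcoxon_rank_sum"))
        pc$epoch_a <- eps[i]; pc$epoch_b <- eps[j]
        pc$median_a <- median(a, na.rm = TRUE)
        pc$median_b <- median(b, na.rm = TRUE)
        cmp[[length(cmp) + 1L]] <- pc
      }
    }
    if (length(cmp)) pfs_comparison <- bind_rows(cmp)
  }
  # --- decoding -------------------------------------------------------
  decoding <- NULL
  if (cfg$decode && "CO" %in% names(trials_by_epoch)) {
    decoding <- tryCatch({
      tr <- trials_by_epoch$CO
      tr <- tr[tr$direction == "right", ]
      lab <- label_trials(tr, threshold_rule = cfg$threshold_rule)
      feats <- pre_entry_rates(lab, spikes, linpos_by_epoch$CO, session$maze,
                               bin_width = cfg$bin_width)
      if (length(unique(lab$label)) < 2)
        abort("single-class session.", class = "elmaze_degenerate_session")
      ps <- pair_search(feats)
      sh <- shuffle_test(feats, pair = ps$best_pair,
                         n_shuffles = cfg$n_shuffles,
                         seed = child_seed(cfg$seed, "shuffle"))
      list(labels = lab, threshold_bin = attr(lab, "threshold_bin"),
           pair_search = ps, shuffle = sh,
           successful = sh$significant)
    }, error = function(c) {
      skipped$decoding <<- conditionMessage(c)
      NULL
    })
  } else if (cfg$decode) skipped$decoding <- "no CO epoch"
  structure(list(
    behaviour = bind_rows(behaviour),
    trials = trials_by_epoch,
    metrics = metrics, pfs = pfs_tbl, pfs_comparison = pfs_comparison,
    proportions = proportions, speed_glm = glm_tbl,
    swr = swr, decoding = decoding,
    skipped = skipped, config = unclass(cfg)
  ), class = "elm_report")
}

#' @export
print.elm_report <- function(x, ...) {
  cat("<elm_report>\n")
  cat(" epochs:", paste(unique(x$behaviour$epoch), collapse = ", "), "\n")
  if (!is.null(x$metrics))
    cat(sprintf(" %d unit-epoch spatial metric rows\n", nrow(x$metrics)))
  if (!is.null(x$swr)) cat(sprintf(" %d ripple events\n", nrow(x$swr)))
  if (!is.null(x$decoding))
    cat(sprintf(" decoding: best pair (%s, %s), perf %.3f, %s\n",
                x$decoding$pair_search$best_pair[1],
                x$decoding$pair_search$best_pair[2],
                x$decoding$pair_search$best_performance,
                if (x$decoding$successful) "successful" else "not successful"))
  if (length(x$skipped))
    cat(" skipped:", paste(names(x$skipped), unlist(x$skipped),
                           sep = " - ", collapse = "; "), "\n")
  invisible(x)
}

#' Serialise a report to a JSON string
#'
#' Deterministic serialisation (fixed 10 significant digits, stable key
#' order from the report structure): identical sessions, configurations
#' and seeds give byte-identical JSON.
#'
#' @param report An `elm_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  clean <- rapply(unclass(report), function(x) x, how = "replace")
  as.character(jsonlite::toJSON(clean, digits = 10, auto_unbox = TRUE,
                                null = "null", na = "null", force = TRUE))
}

#' Write a report to a JSON file
#'
#' @param report An `elm_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  writeLines(report_json(report), path)
  invisible(path)
}

# ---------------------------------------------------------------------
# Session bundle I/O: tracking CSV (time_s,x_cm,y_cm,valid), spikes CSV
# (unit_id,time_s), units CSV, LFP sample CSV, session.yaml, truth.json.
# Numerics are written as %.17g so a write -> read round trip is exact.

write_exact_csv <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.integer(col)) as.character(col)
    else if (is.numeric(col)) sprintf("%.17g", col)
    else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1, dimnames = list(NULL, names(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(fmt, 1, paste, collapse = ","))
  writeLines(lines, path)
}

read_exact_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Write a session bundle to a directory
#'
#' Layout: `tracking.csv`, `spikes.csv`, `units.csv`, `lfp.csv` (one
#' sample per row), `session.yaml` (maze, epochs, LFP metadata) and
#' `truth.json` when ground truth is present. All files are plain text;
#' numeric columns round-trip exactly.
#'
#' @param session An `elm_session`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_exact_csv(session$tracking, file.path(dir, "tracking.csv"))
  write_exact_csv(session$spikes, file.path(dir, "spikes.csv"))
  write_exact_csv(session$units, file.path(dir, "units.csv"))
  meta <- list(
    maze = unclass(session$maze),
    epochs = lapply(seq_len(nrow(session$epochs)), function(i)
      as.list(session$epochs[i, ]))
  )
  if (!is.null(session$lfp)) {
    write_exact_csv(tibble(lfp = session$lfp$trace), file.path(dir, "lfp.csv"))
    meta$lfp <- list(fs = session$lfp$fs, t0 = session$lfp$t0)
  }
  yaml::write_yaml(meta, file.path(dir, "session.yaml"))
  if (!is.null(session$truth)) {
    jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE, null = "null",
                         na = "null", force = TRUE)
  }
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Inverse of [write_session()]. Spike tables with unordered times are
#' sorted on read with a warning.
#'
#' @param dir Bundle directory.
#' @return An `elm_session` (the truth record, if present, is returned
#'   as plain parsed JSON).
#' @export
read_session <- function(dir) {
  need <- c("tracking.csv", "spikes.csv", "units.csv", "session.yaml")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    abort(paste("missing session files:", paste(miss, collapse = ", ")),
          class = "elmaze_data_error")
  tracking <- read_exact_csv(file.path(dir, "tracking.csv"))
  spikes <- read_exact_csv(file.path(dir, "spikes.csv"))
  if (nrow(spikes) > 1 && is.unsorted(order(spikes$unit_id, spikes$time_s))) {
    o <- order(spikes$unit_id, spikes$time_s)
    if (!identical(o, seq_len(nrow(spikes)))) {
      warn("spike table was unordered; sorted on read.")
      spikes <- spikes[o, ]
    }
  }
  units <- read_exact_csv(file.path(dir, "units.csv"))
  meta <- yaml::read_yaml(file.path(dir, "session.yaml"))
  maze <- do.call(maze_spec, meta$maze[c("kind", "configuration",
                                         "track_length", "track_width",
                                         "reward_zone_length",
                                         "epm_arm_length", "epm_arm_width")])
  maze$centre_zone_width <- meta$maze$centre_zone_width
  epochs <- bind_rows(lapply(meta$epochs, as_tibble))
  lfp <- NULL
  if (file.exists(file.path(dir, "lfp.csv"))) {
    lfp <- list(trace = read_exact_csv(file.path(dir, "lfp.csv"))$lfp,
                fs = meta$lfp$fs, t0 = meta$lfp$t0, events = NULL)
  }
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  else NULL
  structure(list(tracking = tracking, spikes = spikes, units = units,
                 lfp = lfp, epochs = epochs, maze = maze, truth = truth),
            class = "elm_session")
}
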