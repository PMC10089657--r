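# Prediction of open-arm exploration extent from pre-entry population
# activity: trial labelling, feature extraction, linear-SVM LOOCV,
# exhaustive pair wrapper, and a label-permutation null.

#' Label open-arm trials as proximal or distal
#'
#' The per-session threshold is the middle of the explored range:
#' `nearest + (furthest - nearest) / 2` in spatial-bin units, where
#' nearest/furthest are the extremes of `furthest_bin` over the session's
#' toward-open trials (`threshold_rule = "midpoint"`). The literal
#' half-range reading `(furthest - nearest) / 2` is available as
#' `"half_range"`. Trials reaching at least the threshold bin are labelled
#' distal (boundary trials count as distal).
#'
#' @param trials Trial table (see [segment_trials()]) already filtered to
#'   the toward-open direction.
#' @param threshold_rule `"midpoint"` (default) or `"half_range"`.
#' @return The trials tibble with a `label` column (`"proximal"` /
#'   `"distal"`) and attributes `threshold_bin`, `nearest_bin`,
#'   `furthest_bin`.
#' @export
label_trials <- function(trials, threshold_rule = c("midpoint", "half_range")) {
  threshold_rule <- match.arg(threshold_rule)
  if (nrow(trials) < 2) abort("need at least 2 trials to label.",
                              class = "elmaze_insufficient_data")
  nearest <- min(trials$furthest_bin); furthest <- max(trials$furthest_bin)
  if (furthest <= nearest)
    abort("all trials reach the same furthest bin: labelling degenerate.",
          class = "elmaze_degenerate_session")
  thr <- switch(threshold_rule,
                midpoint = nearest + (furthest - nearest) / 2,
                half_range = (furthest - nearest) / 2)
  trials$label <- ifelse(trials$furthest_bin >= thr, "distal", "proximal")
  attr(trials, "threshold_bin") <- thr
  attr(trials, "nearest_bin") <- nearest
  attr(trials, "furthest_bin") <- furthest
  trials
}

#' Pre-entry firing rates per trial and unit
#'
#' For each toward-open trial, the approach window runs from the trial
#' start (the moment the animal heads toward the open arm after leaving
#' the reward zone) until it reaches the spatial bin before the track
#' centre, i.e. until the linear position first reaches
#' `middle - bin_width`. Each unit's feature is its spike count in the
#' window divided by the window duration (Hz). Trials with a
#' non-positive window are excluded (recorded in attribute
#' `excluded_trials`).
#'
#' @param trials Labelled toward-open trials ([label_trials()] output).
#' @param spikes Spike table (`unit_id`, `time_s`).
#' @param linpos [linearize_elm()] output.
#' @param maze The ELM [maze_spec()].
#' @param bin_width Spatial bin (cm) defining "the bin before the centre".
#' @return Tibble: `trial_id`, `label`, `window_start_s`, `window_end_s`,
#'   then one `u<unit_id>` rate column per unit (sorted unit order).
#' @export
pre_entry_rates <- function(trials, spikes, linpos, maze, bin_width = 2.5) {
  boundary <- maze$middle - bin_width
  units <- sort(unique(spikes$unit_id))
  rows <- list(); excluded <- integer()
  for (k in seq_len(nrow(trials))) {
    t0 <- trials$start_s[k]; t1 <- trials$end_s[k]
    seg <- linpos[linpos$time_s >= t0 & linpos$time_s <= t1, ]
    hit <- which(seg$pos_cm >= boundary)
    tend <- if (length(hit)) seg$time_s[hit[1]] else t1
    dur <- tend - t0
    if (dur <= 0) { excluded <- c(excluded, trials$trial_id[k]); next }
    rates <- vapply(units, function(u) {
      st <- spikes$time_s[spikes$unit_id == u]
      sum(st >= t0 & st < tend) / dur
    }, numeric(1))
    rows[[length(rows) + 1L]] <- c(trial_id = trials$trial_id[k],
                                   window_start_s = t0, window_end_s = tend,
                                   setNames(rates, paste0("u", units)))
  }
  if (length(rows) == 0)
    abort("no trial had a usable pre-entry window.",
          class = "elmaze_insufficient_data")
  out <- as_tibble(as.data.frame(do.call(rbind, rows)))
  out$label <- trials$label[match(out$trial_id, trials$trial_id)]
  out <- out[, c("trial_id", "label", "window_start_s", "window_end_s",
                 paste0("u", units))]
  attr(out, "excluded_trials") <- excluded
  out
}

# Direct decision-value prediction for a two-class linear-kernel e1071
# fit: sign(w . x_scaled - rho) picks the first training label. Identical
# to predict.svm for the linear kernel (cross-checked in the tests), but
# without the dispatch/validation overhead, which matters inside
# permutation loops.
svm_linear_predict <- function(fit, xnew) {
  if (!is.null(fit$x.scale))
    xnew <- (xnew - fit$x.scale[[1]]) / fit$x.scale[[2]]
  dv <- sum((t(fit$coefs) %*% fit$SV) * xnew) - fit$rho
  lev <- fit$levels[fit$labels]
  if (dv > 0) lev[1] else lev[2]
}

# Feature-matrix accessor: the u<id> columns of a pre_entry_rates tibble.
feature_matrix <- function(features) {
  cols <- grep("^u", names(features), value = TRUE)
  as.matrix(features[, cols, drop = FALSE])
}

#' Leave-one-out cross-validated linear SVM performance
#'
#' For each trial, a linear-kernel SVM (cost 1, features standardised by
#' the training fold) is trained on all remaining trials and predicts the
#' held-out trial; performance is the fraction of correct predictions.
#' Training folds that contain a single class fall back to a majority
#' prediction with a warning.
#'
#' @param features Numeric matrix or data frame of predictors (rows =
#'   trials); `u*` columns are used if a [pre_entry_rates()] tibble is
#'   passed.
#' @param labels Character/factor vector of trial labels.
#' @param cost SVM regularisation constant (default 1).
#' @param scale Standardise features on each training fold (default TRUE).
#' @return Performance in `[0, 1]`.
#' @export
loocv_svm <- function(features, labels, cost = 1, scale = TRUE) {
  x <- if (is.data.frame(features) && any(grepl("^u", names(features))))
    feature_matrix(features) else as.matrix(features)
  y <- as.character(labels)
  n <- nrow(x)
  if (n < 4) abort("need at least 4 trials for leave-one-out evaluation.",
                   class = "elmaze_insufficient_data")
  if (length(unique(y)) < 2)
    abort("both labels must be present.", class = "elmaze_insufficient_data")
  correct <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      warn("single-class training fold: majority prediction used.")
      pred <- names(which.max(table(ytr)))
    } else {
      # constant-feature scaling warnings from degenerate folds are benign
      fit <- suppressWarnings(
        e1071::svm(x[-i, , drop = FALSE], factor(ytr),
                   kernel = "linear", cost = cost, scale = scale,
                   fitted = FALSE))
      pred <- svm_linear_predict(fit, x[i, ])
    }
    if (pred == y[i]) correct <- correct + 1L
  }
  correct / n
}

#' Wrapper search over all unit pairs
#'
#' Evaluates the leave-one-out SVM performance of every one of the
#' `C(n, 2)` unit pairs and returns the best (ties broken to the
#' lexicographically first pair). Sessions with fewer than 3 units are
#' excluded.
#'
#' @param features [pre_entry_rates()] tibble (or matrix with named
#'   columns).
#' @param labels Trial labels (taken from the `label` column when
#'   `features` carries one and `labels` is missing).
#' @inheritParams loocv_svm
#' @return Object of class `pair_search`: `best_pair` (character 2),
#'   `best_performance`, `table` (tibble `unit_a, unit_b, performance`).
#' @export
pair_search <- function(features, labels = NULL, cost = 1, scale = TRUE) {
  if (is.null(labels) && is.data.frame(features) && "label" %in% names(features))
    labels <- features$label
  x <- if (is.data.frame(features) && any(grepl("^u", names(features))))
    feature_matrix(features) else as.matrix(features)
  if (ncol(x) < 3)
    abort("fewer than 3 co-recorded units: session excluded.",
          class = "elmaze_session_excluded")
  pairs <- combn(colnames(x), 2)
  perf <- vapply(seq_len(ncol(pairs)), function(k)
    loocv_svm(x[, pairs[, k], drop = FALSE], labels, cost = cost,
              scale = scale), numeric(1))
  best <- which.max(perf)   # first max = lexicographic tie-break
  structure(list(
    best_pair = pairs[, best],
    best_performance = perf[best],
    table = tibble(unit_a = pairs[1, ], unit_b = pairs[2, ],
                   performance = perf)
  ), class = "pair_search")
}

#' @export
print.pair_search <- function(x, ...) {
  cat(sprintf("<pair_search> %d pairs; best (%s, %s) at %.3f\n",
              nrow(x$table), x$best_pair[1], x$best_pair[2],
              x$best_performance))
  invisible(x)
}

#' Permutation test of decoding performance
#'
#' Because proximal and distal trial counts are not balanced, observed
#' performance is compared against a null built by permuting the trial
#' labels (preserving the class imbalance exactly) and repeating the
#' leave-one-out evaluation on the same feature pair. The session's
#' decoding is deemed successful when the observed performance exceeds
#' the 95th percentile of the null. The observed-minus-null differential
#' series is also returned.
#'
#' @param features Feature matrix or [pre_entry_rates()] tibble restricted
#'   to the chosen pair (extra `u*` columns are allowed if `pair` is
#'   given).
#' @param labels Trial labels (default: `label` column).
#' @param pair Optional character 2-vector naming the feature columns.
#' @param n_shuffles Number of permutations (default 1000; < 100 warns).
#' @param seed Mandatory integer seed.
#' @inheritParams loocv_svm
#' @return Object of class `svm_shuffle_test`: `observed`, `null`
#'   (length `n_shuffles`), `q95`, `differential`, `significant`.
#' @export
shuffle_test <- function(features, labels = NULL, pair = NULL,
                         n_shuffles = 1000, seed, cost = 1, scale = TRUE) {
  if (missing(seed)) abort("`seed` is required for a reproducible null.",
                           class = "elmaze_parameter_error")
  if (n_shuffles < 100) warn("fewer than 100 shuffles gives a coarse null.")
  if (is.null(labels) && is.data.frame(features) && "label" %in% names(features))
    labels <- features$label
  x <- if (is.data.frame(features) && any(grepl("^u", names(features))))
    feature_matrix(features) else as.matrix(features)
  if (!is.null(pair)) x <- x[, pair, drop = FALSE]
  observed <- loocv_svm(x, labels, cost = cost, scale = scale)
  null <- with_seed(child_seed(seed, "shuffle"), {
    vapply(seq_len(n_shuffles), function(k)
      loocv_svm(x, sample(labels), cost = cost, scale = scale), numeric(1))
  })
  q95 <- quantile(null, 0.95, names = FALSE)
  structure(list(observed = observed, null = null, q95 = q95,
                 differential = observed - null,
                 significant = observed > q95,
                 n_shuffles = n_shuffles, seed = seed),
            class = "svm_shuffle_test")
}

#' @export
print.svm_shuffle_test <- function(x, ...) {
  cat(sprintf("<svm_shuffle_test> observed %.3f vs null 95th pct %.3f (%d shuffles): %s\n",
              x$observed, x$q95, x$n_shuffles,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
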