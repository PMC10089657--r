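# Broom-style tidiers for the package's fitted objects.

#' Tidy a speed-model fit
#'
#' @param x A [fit_speed_glm()] object.
#' @param ... Unused.
#' @return One row per model term: `term, estimate, std.error, p.value`.
#' @export
tidy.speed_glm <- function(x, ...) {
  tibble(term = c("(Intercept)", "speed"),
         estimate = unname(x$coefficients),
         std.error = c(NA_real_, x$se),
         p.value = c(NA_real_, x$p_value))
}

#' @rdname tidy.speed_glm
#' @return For `glance()`: one row with `b0, b1, p.value, n_bins,
#'   bin_width_s, significant`.
#' @export
glance.speed_glm <- function(x, ...) {
  tibble(b0 = unname(x$coefficients["b0"]),
         b1 = unname(x$coefficients["b1"]),
         p.value = x$p_value, n_bins = nrow(x$bins),
         bin_width_s = x$bin_width,
         significant = speed_modulation_significant(x))
}

#' Tidy a decoding permutation test
#'
#' @param x A [shuffle_test()] object.
#' @param ... Unused.
#' @return One row per permutation: `shuffle, performance, differential`.
#' @export
tidy.svm_shuffle_test <- function(x, ...) {
  tibble(shuffle = seq_along(x$null), performance = x$null,
         differential = x$differential)
}

#' @rdname tidy.svm_shuffle_test
#' @return For `glance()`: `observed, null_q95, null_median, significant,
#'   n_shuffles`.
#' @export
glance.svm_shuffle_test <- function(x, ...) {
  tibble(observed = x$observed, null_q95 = x$q95,
         null_median = median(x$null), significant = x$significant,
         n_shuffles = x$n_shuffles)
}

#' Tidy a wrapper pair search
#'
#' @param x A [pair_search()] object.
#' @param ... Unused.
#' @return The per-pair performance table with a `best` flag.
#' @export
tidy.pair_search <- function(x, ...) {
  out <- x$table
  out$best <- out$unit_a == x$best_pair[1] & out$unit_b == x$best_pair[2]
  out
}

#' @rdname tidy.pair_search
#' @export
glance.pair_search <- function(x, ...) {
  tibble(unit_a = x$best_pair[1], unit_b = x$best_pair[2],
         best_performance = x$best_performance, n_pairs = nrow(x$table))
}

#' Tidy a peak-density bootstrap test
#'
#' @param x A [peak_density_bootstrap()] object.
#' @param ... Unused.
#' @return Per-bin tibble: observed density, null median and quantile,
#'   significance flag.
#' @export
tidy.peak_density_test <- function(x, ...) {
  out <- x$observed
  out$null_median <- x$null_median
  out$null_quantile <- x$null_quantile
  out$significant <- x$significant
  out
}

#' @rdname tidy.peak_density_test
#' @export
glance.peak_density_test <- function(x, ...) {
  tibble(n_bins = nrow(x$observed), n_significant = sum(x$significant),
         n_shuffles = x$n_shuffles, alpha = x$alpha)
}
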