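#' Chi-square test on peak-location proportions
#'
#' One-sample goodness-of-fit of observed per-region peak counts against
#' expected proportions, in one of two modes: `"even"` assumes equal
#' chance per region (50/50 for two halves), `"reference"` takes the
#' expected proportions from a reference condition's counts (e.g. the
#' closed-closed configuration).
#'
#' @param counts Named or unnamed non-negative integer vector of observed
#'   peak counts per region.
#' @param mode `"even"` or `"reference"`.
#' @param reference Counts (or proportions) defining the expectation in
#'   `"reference"` mode.
#' @return Tibble `statistic, df, p_value, n, mode`.
#' @examples
#' proportion_test(c(70, 30)) # chi-square 16 against 50/50
#' @export
proportion_test <- function(counts, mode = c("even", "reference"),
                            reference = NULL) {
  mode <- match.arg(mode)
  if (any(counts < 0) || sum(counts) == 0)
    abort("counts must be non-negative with a positive total.",
          class = "elmaze_parameter_error")
  p <- switch(mode,
              even = rep(1 / length(counts), length(counts)),
              reference = {
                if (is.null(reference))
                  abort("`reference` needed in reference mode.",
                        class = "elmaze_parameter_error")
                if (any(reference <= 0))
                  abort("reference expectation contains a zero count.",
                        class = "elmaze_parameter_error")
                reference / sum(reference)
              })
  ct <- suppressWarnings(stats::chisq.test(x = counts, p = p))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, n = sum(counts), mode = mode)
}

#' Nonparametric paired / unpaired comparison
#'
#' Thin wrapper over the two-sided Wilcoxon tests used for spatial
#' properties (signed-rank, paired) and for comparing distributions
#' across conditions (rank-sum, unpaired).
#'
#' @param values_a,values_b Numeric vectors (equal length when paired).
#' @param test `"wilcoxon_signed_rank"` (paired) or
#'   `"wilcoxon_rank_sum"`.
#' @return Tibble `test, n_a, n_b, statistic, p_value`.
#' @export
paired_compare <- function(values_a, values_b,
                           test = c("wilcoxon_signed_rank",
                                    "wilcoxon_rank_sum")) {
  test <- match.arg(test)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (min(length(values_a), length(values_b)) < 5)
    warn("fewer than 5 observations: test has little power.")
  wt <- if (test == "wilcoxon_signed_rank") {
    if (length(values_a) != length(values_b))
      abort("paired test needs equal-length vectors.",
            class = "elmaze_parameter_error")
    if (all(values_a == values_b))      # all differences zero: no effect
      return(tibble(test = test, n_a = length(values_a),
                    n_b = length(values_b), statistic = 0, p_value = 1))
    suppressWarnings(stats::wilcox.test(values_a, values_b, paired = TRUE,
                                        exact = FALSE))
  } else {
    suppressWarnings(stats::wilcox.test(values_a, values_b, paired = FALSE,
                                        exact = FALSE))
  }
  tibble(test = test, n_a = length(values_a), n_b = length(values_b),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}
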