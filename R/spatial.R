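#' Per-neuron spatial statistics of a rate map
#'
#' Computes the three classical place-field statistics over the visited
#' bins of an occupancy-normalised map:
#'
#' * spatial information (bits/spike):
#'   `SI = sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)` with
#'   `lambda = sum_i p_i lambda_i` the overall rate and the `0 log 0 := 0`
#'   convention;
#' * sparsity (coverage): `(sum_i p_i lambda_i)^2 / sum_i p_i lambda_i^2`,
#'   1 for uniform firing, small for compact fields;
#' * coherence: the Fisher z-transform `Z = 0.5 ln((1+R)/(1-R))` of the
#'   correlation `R` between the raw and the smoothed rates — how well a
#'   bin's rate is predicted by its neighbourhood.
#'
#' When the overall rate is zero, SI and sparsity are undefined and
#' returned as `NA` with `undefined = TRUE` (no error). Coherence needs
#' at least 3 visited bins.
#'
#' @param map A `linear_rate_map` (single direction) or `rate_map_2d`.
#' @param coherence Correlation used for R: `"pearson"` (default) or
#'   `"spearman"`; `"none"` skips coherence (allowing maps with fewer
#'   than 3 visited bins). `neighbour = TRUE` correlates the raw rates
#'   against the first-neighbour average instead of the Gaussian-smoothed
#'   map.
#' @param neighbour Use first-neighbour averaging for coherence.
#' @return One-row tibble: `mean_rate_hz, si_bits, sparsity, coherence_r,
#'   coherence_z, n_bins, undefined`.
#' @export
spatial_stats <- function(map, coherence = c("pearson", "spearman", "none"),
                          neighbour = FALSE) {
  coherence <- match.arg(coherence)
  if ("direction" %in% names(map) && length(unique(map$direction)) > 1)
    abort("map contains multiple directions; filter to one first.",
          class = "elmaze_parameter_error")
  v <- map$visited & !is.na(map$rate_raw)
  p <- map$p_occ[v]; lam_i <- map$rate_raw[v]
  lam <- sum(p * lam_i)
  if (coherence != "none" && sum(v) < 3)
    abort("need at least 3 visited bins for coherence.",
          class = "elmaze_insufficient_bins")
  if (lam <= 0) {
    si <- NA_real_; sp <- NA_real_; undef <- TRUE
  } else {
    ratio <- lam_i / lam
    terms <- ifelse(lam_i > 0, p * ratio * log2(ratio), 0)
    si <- sum(terms)
    sp <- lam^2 / sum(p * lam_i^2)
    undef <- FALSE
  }
  if (coherence == "none") {
    r <- NA_real_; z <- NA_real_
  } else {
    smoothed <- if (neighbour) neighbour_average(map)[v] else map$rate_smooth[v]
    r <- suppressWarnings(cor(lam_i, smoothed, method = coherence))
    if (is.na(r)) {
      z <- NA_real_
    } else {
      r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
      z <- 0.5 * log((1 + r) / (1 - r))
    }
  }
  tibble(mean_rate_hz = lam, si_bits = si, sparsity = sp,
         coherence_r = r, coherence_z = z, n_bins = sum(v),
         undefined = undef)
}

# First-neighbour average of raw rates (visited neighbours only), the
# Muller-Kubie coherence tradition, for 1D maps.
neighbour_average <- function(map) {
  x <- ifelse(map$visited, map$rate_raw, NA_real_)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- c(if (i > 1) x[i - 1], if (i < n) x[i + 1])
    nb <- nb[!is.na(nb)]
    if (length(nb)) out[i] <- mean(nb)
  }
  out
}

#' Place-field similarity between the two running directions
#'
#' The Spearman rank correlation (average ranks for ties) between a
#' neuron's z-scored linear rate maps for the two running directions,
#' computed over the bins visited in both directions. High PFS means the
#' neuron fires in the same places regardless of heading
#' (direction-homogenised activity).
#'
#' @param map_dir1,map_dir2 Z-transformed single-direction maps
#'   (see [z_transform()]) on the same bin grid.
#' @return Tibble `pfs, n_bins_used, undefined`; `undefined = TRUE` (with
#'   `pfs = NA`) when either map is constant over the common bins.
#' @export
pfs <- function(map_dir1, map_dir2) {
  if (nrow(map_dir1) != nrow(map_dir2) ||
      any(map_dir1$bin != map_dir2$bin))
    abort("maps must share an identical bin grid.",
          class = "elmaze_parameter_error")
  if (!"rate_z" %in% names(map_dir1) || !"rate_z" %in% names(map_dir2))
    abort("maps must be z-transformed first (see z_transform()).",
          class = "elmaze_parameter_error")
  common <- map_dir1$visited & map_dir2$visited
  n <- sum(common)
  if (n < 3) abort("fewer than 3 bins visited in both directions.",
                   class = "elmaze_insufficient_bins")
  a <- map_dir1$rate_z[common]; b <- map_dir2$rate_z[common]
  if (sd(a) == 0 || sd(b) == 0)
    return(tibble(pfs = NA_real_, n_bins_used = n, undefined = TRUE))
  tibble(pfs = cor(a, b, method = "spearman"), n_bins_used = n,
         undefined = FALSE)
}

#' Rate-remapping score between two epochs
#'
#' A normalised rate difference `|m_a - m_b| / (m_a + m_b)` on the
#' occupancy-weighted mean rates of the same neuron's maps in two epochs:
#' 0 for identical mean rates, 1 when the neuron is silent in one epoch.
#'
#' @param map_a,map_b Rate maps of one neuron in two epochs, same grid.
#' @return Tibble `score, mean_rate_a, mean_rate_b, undefined`
#'   (`undefined` when both epochs are silent).
#' @export
rate_remapping_score <- function(map_a, map_b) {
  m <- function(mp) {
    v <- mp$visited & !is.na(mp$rate_raw)
    sum(mp$p_occ[v] * mp$rate_raw[v])
  }
  ma <- m(map_a); mb <- m(map_b)
  if (ma + mb == 0)
    return(tibble(score = NA_real_, mean_rate_a = ma, mean_rate_b = mb,
                  undefined = TRUE))
  tibble(score = abs(ma - mb) / (ma + mb), mean_rate_a = ma,
         mean_rate_b = mb, undefined = FALSE)
}

#' Density of peak firing locations over spatial bins
#'
#' For each bin, the number of neurons whose peak firing falls there
#' divided by the number of neurons with any activity in that bin (a bin
#' with 20 peaks and 100 active neurons has density 0.2). Bins where no
#' neuron is active are masked.
#'
#' @param peaks Data frame with one row per neuron: `unit_id`, `peak_bin`
#'   (integer) and a list-column `active_bins` of integer vectors (the
#'   bins in which that neuron has activity).
#' @param n_bins Total number of spatial bins.
#' @return Tibble `bin, n_peaks, n_active, density` (`density` `NA` where
#'   `n_active == 0`).
#' @export
peak_density <- function(peaks, n_bins) {
  stopifnot(is.data.frame(peaks), all(c("unit_id", "peak_bin", "active_bins")
                                      %in% names(peaks)))
  ok <- mapply(function(p, a) p %in% a, peaks$peak_bin, peaks$active_bins)
  if (!all(ok))
    abort("each neuron's peak must lie in one of its active bins.",
          class = "elmaze_consistency_error")
  n_peaks <- tabulate(peaks$peak_bin, nbins = n_bins)
  n_active <- tabulate(unlist(peaks$active_bins), nbins = n_bins)
  tibble(bin = seq_len(n_bins), n_peaks = n_peaks, n_active = n_active,
         density = ifelse(n_active > 0, n_peaks / n_active, NA_real_))
}

#' Bootstrap null for the peak-density map
#'
#' Builds a per-bin null by reassigning every neuron's peak uniformly at
#' random over that neuron's own visited (active) bins, recomputing the
#' density map each time. A bin is flagged significant when its observed
#' density exceeds the `1 - alpha` percentile of its null densities
#' (one-tailed, per bin, no multiplicity correction).
#'
#' @inheritParams peak_density
#' @param n_shuffles Number of reassignments (default 1000; fewer than
#'   100 draws a warning).
#' @param alpha One-tailed level (default 0.05).
#' @param seed Mandatory integer seed.
#' @return Object of class `peak_density_test`; see [tidy.peak_density_test()].
#' @export
peak_density_bootstrap <- function(peaks, n_bins, n_shuffles = 1000,
                                   alpha = 0.05, seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible null.",
                           class = "elmaze_parameter_error")
  if (n_shuffles < 100) warn("fewer than 100 shuffles gives a coarse null.")
  obs <- peak_density(peaks, n_bins)
  n_neurons <- nrow(peaks)
  draws <- with_seed(child_seed(seed, "bootstrap"), {
    vapply(peaks$active_bins, function(a)
      if (length(a) == 1) rep(a, n_shuffles)
      else sample(a, n_shuffles, replace = TRUE),
      integer(n_shuffles))
  })
  # draws: n_shuffles x n_neurons; per-shuffle per-bin peak counts
  flat <- as.vector(t(draws)) + n_bins * rep(0:(n_shuffles - 1), each = n_neurons)
  counts <- matrix(tabulate(flat, nbins = n_bins * n_shuffles),
                   nrow = n_bins)
  dens_null <- counts / ifelse(obs$n_active > 0, obs$n_active, NA_real_)
  q <- med <- rep(NA_real_, n_bins)
  act <- obs$n_active > 0
  if (any(act)) {
    q[act] <- apply(dens_null[act, , drop = FALSE], 1, quantile,
                    probs = 1 - alpha, names = FALSE)
    med[act] <- apply(dens_null[act, , drop = FALSE], 1, median)
  }
  sig <- !is.na(obs$density) & obs$density > q
  structure(list(
    observed = obs,
    null_quantile = q, null_median = med,
    significant = sig, n_shuffles = n_shuffles, alpha = alpha, seed = seed
  ), class = "peak_density_test")
}

#' @export
print.peak_density_test <- function(x, ...) {
  cat(sprintf("<peak_density_test> %d bins, %d shuffles, alpha %.2f: %d significant bin(s)\n",
              nrow(x$observed), x$n_shuffles, x$alpha, sum(x$significant)))
  invisible(x)
}
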