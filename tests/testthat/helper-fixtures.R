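# Fixture builders and independent brute-force oracles shared by the
# suite. Oracles are deliberately naive re-derivations of the printed
# formulas, never calls into the code paths they check.

# Linearised-position tibble from a bare position series (50 fps).
make_linpos <- function(pos, fps = 50, direction = NULL) {
  n <- length(pos)
  if (is.null(direction)) {
    d <- c(0, diff(pos))
    dir <- ifelse(d >= 0, "right", "left")
  } else dir <- rep(direction, length.out = n)
  tibble::tibble(time_s = (seq_len(n) - 1) / fps, pos_cm = pos,
                 direction = dir, speed_cms = c(0, abs(diff(pos)) * fps))
}

# Tracking tibble from x positions (y = 0).
make_tracking <- function(x, fps = 50, y = 0) {
  tibble::tibble(time_s = (seq_along(x) - 1) / fps, x_cm = x,
                 y_cm = rep(y, length.out = length(x)), valid = TRUE)
}

# Hand-assembled rate-map tibble for metric tests.
make_map <- function(rate_raw, p_occ = NULL, rate_smooth = NULL,
                     visited = NULL, occupancy = NULL) {
  n <- length(rate_raw)
  if (is.null(visited)) visited <- rep(TRUE, n)
  if (is.null(p_occ)) p_occ <- ifelse(visited, 1 / sum(visited), NA_real_)
  if (is.null(rate_smooth)) rate_smooth <- rate_raw
  if (is.null(occupancy)) occupancy <- ifelse(visited, 1, 0)
  tibble::tibble(bin = seq_len(n), lo_cm = (seq_len(n) - 1) * 2.5,
                 hi_cm = seq_len(n) * 2.5, occupancy_s = occupancy,
                 p_occ = p_occ, n_spikes = 0L, rate_raw = rate_raw,
                 rate_smooth = rate_smooth, visited = visited)
}

# --- formula oracles --------------------------------------------------

si_oracle <- function(p, lam_i) {
  lam <- sum(p * lam_i)
  if (lam <= 0) return(NA_real_)
  s <- 0
  for (i in seq_along(p)) {
    if (lam_i[i] > 0) s <- s + p[i] * (lam_i[i] / lam) * log2(lam_i[i] / lam)
  }
  s
}

sparsity_oracle <- function(p, lam_i) {
  lam <- sum(p * lam_i)
  if (lam <= 0) return(NA_real_)
  lam^2 / sum(p * lam_i^2)
}

fisher_z_oracle <- function(r) 0.5 * log((1 + r) / (1 - r))

pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

spearman_oracle <- function(a, b) pearson_oracle(rank(a), rank(b))

chisq_oracle <- function(obs, p_exp) {
  e <- sum(obs) * p_exp
  sum((obs - e)^2 / e)
}

# Explicit leave-one-out loop with the same solver settings as the
# implementation, written independently.
loocv_oracle <- function(x, y, cost = 1, scale = TRUE) {
  hits <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    tr_x <- x[-i, , drop = FALSE]; tr_y <- factor(y[-i])
    if (nlevels(tr_y) < 2) {
      pred <- names(sort(table(tr_y), decreasing = TRUE))[1]
    } else {
      mdl <- suppressWarnings(e1071::svm(tr_x, tr_y, kernel = "linear",
                                         cost = cost, scale = scale))
      pred <- as.character(predict(mdl, x[i, , drop = FALSE]))
    }
    hits[i] <- pred == y[i]
  }
  mean(hits)
}

# 99% central binomial acceptance interval.
binom99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)
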