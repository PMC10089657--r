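# Seed plumbing: one user-facing seed expands into per-component child seeds
# through a fixed affine rule, so adding a component or changing an unrelated
# parameter never reshuffles the streams of the others.

CHILD_SEED_OFFSETS <- c(
  trajectory = 101L,
  spikes     = 211L,
  lfp        = 307L,
  session    = 401L,
  bootstrap  = 503L,
  shuffle    = 601L
)

#' Derive a deterministic child seed
#'
#' Expands a single session seed into independent per-component seeds.
#' The rule is `(seed * 48271 + offset + k) mod (2^31 - 2) + 1`, a
#' Lehmer-style scramble that keeps the result a valid positive 32-bit
#' integer seed.
#'
#' @param seed Integer parent seed.
#' @param component One of `"trajectory"`, `"spikes"`, `"lfp"`, `"session"`,
#'   `"bootstrap"`, `"shuffle"`.
#' @param k Extra index (e.g. unit number) for per-item streams.
#' @return A positive integer seed.
#' @export
child_seed <- function(seed, component, k = 0L) {
  offset <- CHILD_SEED_OFFSETS[[match.arg(component, names(CHILD_SEED_OFFSETS))]]
  m <- 2147483646
  as.integer((as.numeric(seed) * 48271 + offset + as.numeric(k)) %% m + 1)
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
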