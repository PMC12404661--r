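# Independent oracles, deliberately written without reusing package internals.

# Odds-product formulation of the deterministic biphasic dynamics: each
# selection phase multiplies the A:B odds by w/(1-w).
oracle_odds_trajectory <- function(p0, w_w, w_p, n_cycles) {
  odds <- p0 / (1 - p0)
  prop_w <- prop_p <- numeric(n_cycles)
  for (t in seq_len(n_cycles)) {
    odds <- odds * w_w / (1 - w_w)
    prop_w[t] <- odds / (1 + odds)
    odds <- odds * w_p / (1 - w_p)
    prop_p[t] <- odds / (1 + odds)
  }
  list(prop_w = prop_w, prop_p = prop_p)
}

# Brute-force exact two-sided Mann-Whitney p: enumerate every assignment of
# the pooled values into groups of sizes (n1, n2), computing U from pairwise
# comparisons (not ranks).
brute_u_stat <- function(x, y) {
  u_x <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(u_x, length(x) * length(y) - u_x)
}

brute_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- brute_u_stat(x, y)
  idx <- utils::combn(length(pooled), n1)
  stats <- apply(idx, 2, function(s) brute_u_stat(pooled[s], pooled[-s]))
  mean(stats <= obs + 1e-9)
}

# Brute-force exact two-sided signed-rank p: enumerate all sign vectors of
# the nonzero differences.
brute_v_stat <- function(d) {
  r <- rank(abs(d))
  v_plus <- sum(r[d > 0])
  min(v_plus, sum(r) - v_plus)
}

brute_signed_rank_p <- function(x, y) {
  d <- (x - y)[x != y]
  if (length(d) == 0) return(1)
  mags <- abs(d)
  obs <- brute_v_stat(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(d))))
  stats <- apply(signs, 1, function(s) brute_v_stat(s * mags))
  mean(stats <= obs + 1e-9)
}

noiseless_config <- function(...) {
  generator_config(noise_sigma_log = 0, ...)
}
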