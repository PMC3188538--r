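# Independent oracles used across the suite.

# Dense two-stage grid search for the likelihood maximizer, independent of
# the package's optimizer (relative resolution ~2e-6 on m).
grid_mle <- function(cs, lo = 1e-4, hi = 50, n_coarse = 4000, n_fine = 4001) {
  ll <- function(m) log_likelihood(cs, m)
  g1 <- exp(seq(log(lo), log(hi), length.out = n_coarse))
  v1 <- vapply(g1, ll, numeric(1))
  i <- which.max(v1)
  step <- log(g1[2]) - log(g1[1])
  g2 <- exp(seq(log(g1[i]) - step, log(g1[i]) + step, length.out = n_fine))
  v2 <- vapply(g2, ll, numeric(1))
  g2[which.max(v2)]
}

# Profile-likelihood scan for LR interval endpoints: locate sign changes of
# ll(m) - (ll(mhat) - qchisq(level,1)/2) on a fine log grid and refine by
# linear interpolation.
grid_lr_interval <- function(cs, level = 0.95, lo = 1e-8, hi = 500, n = 40000) {
  m_hat <- grid_mle(cs)
  cut <- log_likelihood(cs, m_hat) - qchisq(level, 1) / 2
  g <- exp(seq(log(lo), log(hi), length.out = n))
  f <- vapply(g, function(m) log_likelihood(cs, m), numeric(1)) - cut
  sgn <- sign(f)
  idx <- which(diff(sgn) != 0)
  cross <- vapply(idx, function(i) {
    # linear interpolation in log m
    w <- f[i] / (f[i] - f[i + 1])
    exp(log(g[i]) + w * (log(g[i + 1]) - log(g[i])))
  }, numeric(1))
  lo_end <- if (f[1] >= 0) 0 else min(cross)
  hi_end <- max(cross)
  c(lo_end, hi_end)
}

# Exhaustive minimal-edit placements of a single-base indel: all positions
# where deleting from the longer (or inserting into the shorter) sequence
# reproduces the other.
brute_indel_placements <- function(ref, mut) {
  rs <- strsplit(ref, "")[[1]]
  ms <- strsplit(mut, "")[[1]]
  if (length(rs) == length(ms) + 1) {        # deletion from ref
    ok <- vapply(seq_along(rs), function(i)
      identical(rs[-i], ms), logical(1))
    which(ok)
  } else if (length(ms) == length(rs) + 1) { # insertion into ref
    ok <- vapply(seq_along(ms), function(i)
      identical(ms[-i], rs), logical(1))
    which(ok)
  } else stop("not a single-base indel pair")
}

sim_design_m <- function(m, n_cultures = 9, z = 1) {
  fluctuation_design_m(m = m, n_cultures = n_cultures, n_final = 1e9,
                       plating_fraction = z)
}

test_orf <- function() synthetic_reporter_orf()
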