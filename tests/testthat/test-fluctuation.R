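# Lea-Coulson pmf, maximum-likelihood m, likelihood-ratio intervals,
# rate conversion, and pooling.

test_that("ld_pmf matches its closed-form anchors", {
  expect_equal(ld_pmf(0, 5), c(1, 0, 0, 0, 0, 0))
  expect_equal(ld_pmf(1, 0), exp(-1))
  # frozen pgf-expansion values at m = 1:
  # p1 = m e^-m / 2, p2 = e^-m (m/6 + m^2/8), confirmed by Monte Carlo
  p <- ld_pmf(1, 2)
  expect_equal(p[2], exp(-1) / 2, tolerance = 1e-10)
  expect_equal(p[3], exp(-1) * (1 / 6 + 1 / 8), tolerance = 1e-10)
  # P(0) = e^-m exactly with full plating, strictly decreasing in m
  ms <- c(0.2, 0.5, 1, 2, 5)
  p0 <- vapply(ms, function(m) ld_pmf(m, 0), numeric(1))
  expect_equal(p0, exp(-ms), tolerance = 1e-12)
  expect_true(all(diff(p0) < 0))
})

test_that("ld_pmf input validation", {
  expect_error(ld_pmf(-1, 5), "non-negative")
  expect_error(ld_pmf(1, -1))
  expect_error(ld_pmf(1, 5, 0), "plating_fraction")
  expect_error(ld_pmf(1, 5, 1.2), "plating_fraction")
})

test_that("pmf mass accumulates to 1 as n_max grows", {
  # tail decays like m/n, so the partial sum reaches 1 - m/n_max
  for (m in c(0.5, 2, 8)) {
    s <- sum(ld_pmf(m, ceiling(2000 * m)))
    expect_gte(s, 0.999)
    expect_lte(s, 1 + 1e-12)
  }
})

test_that("thinned pmf equals binomial thinning of the full pmf and Monte Carlo", {
  m <- 1.5; z <- 0.25; kmax <- 8
  # direct convolution oracle over an explicit truncation
  N <- 4000
  p <- ld_pmf(m, N)
  q_oracle <- vapply(0:kmax, function(k) sum(p * dbinom(k, 0:N, z)), numeric(1))
  expect_equal(ld_pmf(m, kmax, z), q_oracle, tolerance = 1e-6)
  # Monte Carlo of the mutation-growth process + thinning
  set.seed(421)
  reps <- 1e5
  nm <- rpois(reps, m)
  full <- vapply(nm, function(k) if (k == 0) 0 else sum(floor(1 / runif(k))), numeric(1))
  obs <- rbinom(reps, size = pmin(full, 2^30), prob = z)
  emp <- tabulate(obs + 1, nbins = kmax + 1) / reps
  se <- sqrt(q_oracle * (1 - q_oracle) / reps)
  expect_true(all(abs(emp - q_oracle) <= 3 * se + 1e-9))
})

test_that("log_likelihood anchors", {
  cs0 <- culture_set(rep(0, 7), n_total = 1e6)
  expect_equal(log_likelihood(cs0, 1), -7)
  cs <- culture_set(c(0, 1), n_total = 1e6)
  expect_equal(log_likelihood(cs, 1), log(exp(-1)) + log(exp(-1) / 2), tolerance = 1e-10)
  expect_identical(log_likelihood(cs, 0), -Inf)
  expect_identical(log_likelihood(cs0, 0), 0)
})

test_that("large jackpot counts use the asymptotic tail without truncation", {
  cs <- culture_set(c(0, 2, 50000), n_total = 1e9)
  ll <- log_likelihood(cs, 1.5)
  expect_true(is.finite(ll))
  # jackpot term ~ log(m/(k(k+1)))
  pm <- ld_pmf(1.5, 2)
  expect_equal(ll, log(pm[1]) + log(pm[3]) + log(1.5 / (50000 * 50001)),
               tolerance = 1e-8)
})

test_that("MLE matches a dense grid-search oracle on fixtures", {
  fixtures <- list(
    culture_set(c(0, 0, 0, 1, 0, 2, 0, 0, 15), n_total = 2e6),
    culture_set(c(0, 0, 1, 1, 0, 0, 0, 0, 0, 3), n_total = 1e6),
    culture_set(c(3, 7, 0, 1, 22, 4, 2, 0, 9), n_total = 5e6),
    culture_set(c(1, 0, 0, 0, 0, 0, 0, 2), n_total = 1e7),
    culture_set(c(12, 40, 5, 8, 31, 2, 19, 7, 3), n_total = 2e6),
    culture_set(c(0, 4, 0, 1, 0, 0, 2, 118, 0), n_total = 2e6),
    culture_set(c(2, 0, 5, 1, 3), n_total = 1e6, plating_fraction = 0.2)
  )
  for (cs in fixtures) {
    m_pkg <- mle_m(cs)$m_hat
    m_grid <- grid_mle(cs)
    expect_equal(m_pkg, m_grid, tolerance = 1e-4)
  }
})

test_that("MLE boundary and degenerate cases", {
  expect_identical(mle_m(culture_set(rep(0, 9), 1e6))$m_hat, 0)
  # single culture allowed
  est <- estimate_rate(culture_set(5, n_total = 1e6))
  expect_true(est$ci_m[1] <= est$m_hat && est$m_hat <= est$ci_m[2])
})

test_that("LR interval endpoints match the profile-likelihood grid scan", {
  fixtures <- list(
    culture_set(c(0, 0, 0, 1, 0, 2, 0, 0, 15), n_total = 2e6),
    culture_set(c(3, 7, 0, 1, 22, 4, 2, 0, 9), n_total = 5e6),
    culture_set(c(0, 0, 1, 1, 0, 0, 0, 0, 0, 3), n_total = 1e6)
  )
  for (cs in fixtures) {
    ci <- lr_interval(cs)
    oracle <- grid_lr_interval(cs)
    expect_equal(ci[1], oracle[1], tolerance = 1e-3)
    expect_equal(ci[2], oracle[2], tolerance = 1e-3)
    expect_true(ci[1] <= mle_m(cs)$m_hat && mle_m(cs)$m_hat <= ci[2])
  }
})

test_that("LR interval at the zero boundary", {
  cs0 <- culture_set(rep(0, 9), n_total = 1e6)
  ci <- lr_interval(cs0)
  expect_identical(ci[1], 0)
  # upper endpoint solves n m = qchisq(.95,1)/2 for all-zero full platings
  expect_equal(ci[2], qchisq(0.95, 1) / 2 / 9, tolerance = 1e-6)
})

test_that("rate scales as 1/Nt with m unchanged", {
  counts <- c(0, 2, 0, 1, 9, 0, 0, 3, 1)
  e1 <- estimate_rate(culture_set(counts, n_total = 1e6))
  e2 <- estimate_rate(culture_set(counts, n_total = 5e6))
  expect_equal(e1$m_hat, e2$m_hat, tolerance = 1e-10)
  expect_equal(e1$rate, 5 * e2$rate, tolerance = 1e-10)
  expect_equal(e1$ci_rate, 5 * e2$ci_rate, tolerance = 1e-8)
})

test_that("pooling merges experiments with <2-fold Nt differences", {
  s1 <- culture_set(c(0, 1, 2), 1.0e6, label = "a")
  s2 <- culture_set(c(3, 0, 0), 1.5e6, label = "b")
  s3 <- culture_set(c(1, 1), 2.5e6, label = "c")
  merged <- pool_experiments(list(s1, s2))
  expect_length(merged, 1)
  expect_equal(merged[[1]]$n_total, 1.25e6)
  expect_equal(sort(merged[[1]]$counts), sort(c(0, 1, 2, 3, 0, 0)))
  expect_null(attr(merged[[1]], "flagged"))

  kept <- pool_experiments(list(s1, s3))
  expect_length(kept, 2)
  expect_true(all(vapply(kept, function(s) isTRUE(attr(s, "flagged")), logical(1))))

  # chain 1.0, 1.4, 1.9: all pairwise ratios < 2 -> one merged set
  s4 <- culture_set(c(1), 1.4e6, label = "d")
  s5 <- culture_set(c(2), 1.9e6, label = "e")
  all3 <- pool_experiments(list(s1, s4, s5))
  expect_length(all3, 1)
  expect_length(all3[[1]]$counts, 5)
})

test_that("culture_set validates its invariants", {
  expect_error(culture_set(integer(0), 1e6), "non-empty")
  expect_error(culture_set(c(-1, 2), 1e6), "non-negative")
  expect_error(culture_set(c(0, 1), 0), "n_total")
  expect_error(culture_set(c(0, 1), 1e6, plating_fraction = 2), "plating_fraction")
})
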