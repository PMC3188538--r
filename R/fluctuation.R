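# Luria-Delbrueck fluctuation analysis: Lea-Coulson pmf, maximum-likelihood
# estimation of m (expected mutations per culture), likelihood-ratio
# confidence intervals, and conversion to per-cell-division rates.

# Counts beyond this index use the large-n asymptotic pn ~ m/(n(n+1))
# instead of the O(n^2) recursion (jackpot cultures).
.LD_RECURSION_CAP <- 5000L

#' Construct a fluctuation-assay culture set
#'
#' One fluctuation experiment: the number of resistant mutant colonies
#' observed in each parallel culture, the total number of cell divisions
#' `n_total` (Nt, taken equal to the final colony-forming-unit count since
#' growth starts from one or few cells), and the fraction of each culture
#' that was plated (accounting for 1:10--1:200 dilutions of strong mutators).
#'
#' @param counts Integer vector of mutant colonies per parallel culture.
#' @param n_total Positive number; total cell divisions per culture (Nt).
#' @param plating_fraction Fraction of each culture plated, in (0, 1].
#' @param label Free-text label (e.g. strain/genotype).
#' @return An object of class `culture_set`.
#' @examples
#' cs <- culture_set(c(0, 0, 1, 0, 3), n_total = 2e6)
#' @export
culture_set <- function(counts, n_total, plating_fraction = 1, label = "") {
  if (length(counts) < 1) stop("counts must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (!is.finite(n_total) || n_total <= 0) stop("n_total must be > 0")
  if (!is.finite(plating_fraction) || plating_fraction <= 0 || plating_fraction > 1)
    stop("plating_fraction must be in (0, 1]")
  structure(
    list(counts = as.integer(counts), n_total = as.numeric(n_total),
         plating_fraction = as.numeric(plating_fraction),
         label = as.character(label)),
    class = "culture_set"
  )
}

#' @export
print.culture_set <- function(x, ...) {
  cat(sprintf("<culture_set> %s: %d cultures, Nt = %.3g, plating fraction = %g\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$counts), x$n_total, x$plating_fraction))
  cat("counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

# Untruncated (plating fraction 1) pmf up to n_max, switching to the
# asymptotic tail pn ~ m/(n(n+1)) beyond the recursion cap.
.ld_pmf_full <- function(m, n_max) {
  cap <- .LD_RECURSION_CAP
  if (n_max <= cap) return(.ld_pmf_msx(m, as.integer(n_max)))
  p <- numeric(n_max + 1)
  p[1:(cap + 1)] <- .ld_pmf_msx(m, cap)
  n <- (cap + 1):n_max
  p[n + 1] <- m / (n * (n + 1))
  p
}

#' Lea-Coulson mutant-count distribution
#'
#' Probability mass function of the number of mutant colonies observed per
#' culture under the Lea-Coulson formulation of the Luria-Delbrueck
#' distribution, computed with the Ma-Sandri-Sarkar recursion (Panjer form
#' of the compound-Poisson law with clone-size distribution
#' \eqn{q_j = 1/(j(j+1))}): \eqn{p_0 = e^{-m}},
#' \eqn{p_n = (m/n) \sum_{j<n} p_j /(n-j+1)}.
#' When only a fraction `plating_fraction` of each culture is plated, the
#' observed counts are the full-culture counts thinned binomially; the
#' returned pmf is the corresponding convolution.
#'
#' @param m Expected number of mutation events per culture (>= 0).
#' @param n_max Largest count to return the probability for.
#' @param plating_fraction Fraction of the culture plated, in (0, 1].
#' @return Numeric vector of length `n_max + 1`; entry `k + 1` is
#'   P(observe k mutant colonies).
#' @examples
#' ld_pmf(1, 5)          # P(0) = exp(-1)
#' ld_pmf(1, 5, 0.1)     # 1:10 dilution
#' @export
ld_pmf <- function(m, n_max, plating_fraction = 1) {
  if (!is.finite(m) || m < 0) stop("m must be a non-negative number")
  if (!is.finite(n_max) || n_max < 0) stop("n_max must be >= 0")
  z <- plating_fraction
  if (!is.finite(z) || z <= 0 || z > 1) stop("plating_fraction must be in (0, 1]")
  n_max <- as.integer(n_max)
  if (m == 0) return(c(1, rep(0, n_max)))
  if (z == 1) return(.ld_pmf_full(m, n_max))
  # Binomial thinning: q_k = sum_n p_n * dbinom(k, n, z). Truncate where the
  # binomial kernel no longer reaches k <= n_max (n z >> n_max).
  n_big <- ceiling((n_max + 10 * sqrt(n_max + 25) + 25) / z)
  p <- .ld_pmf_full(m, n_big)
  n <- 0:n_big
  vapply(0:n_max, function(k) sum(p * dbinom(k, n, z)), numeric(1))
}

#' Log-likelihood of a culture set
#'
#' Sum of log Lea-Coulson probabilities of the observed mutant counts,
#' under the culture set's plating fraction.
#'
#' @param cultures A [culture_set()].
#' @param m Expected mutations per culture (>= 0).
#' @return The log-likelihood; `-Inf` when `m = 0` and any count is positive.
#' @export
log_likelihood <- function(cultures, m) {
  stopifnot(inherits(cultures, "culture_set"))
  if (!is.finite(m) || m < 0) stop("m must be a non-negative number")
  k <- cultures$counts
  if (m == 0) return(if (any(k > 0)) -Inf else 0)
  z <- cultures$plating_fraction
  cap <- .LD_RECURSION_CAP
  small <- k[k <= cap]
  big <- k[k > cap]
  ll <- 0
  if (length(small) > 0) {
    pmf <- ld_pmf(m, max(small), z)
    lp <- log(pmf[small + 1])
    # when entries underflow (huge m relative to the count), substitute the
    # exact large-m leading term log p_k ~ -m + k log(m z q1) - log k!,
    # which keeps the log-likelihood finite and decreasing in m
    bad <- !is.finite(lp) | lp < -690
    if (any(bad)) {
      kb <- small[bad]
      lp[bad] <- -m + kb * log(m * z / 2) - lgamma(kb + 1)
    }
    ll <- ll + sum(lp)
  }
  if (length(big) > 0) {
    # jackpot cultures: large-k asymptotic P(k) ~ m z / (k (k+1)); avoids
    # extending the O(n^2) recursion to extreme counts
    ll <- ll + sum(log(m * z / (big * (big + 1))))
  }
  ll
}

# Starting value: P0 estimator -log(fraction of zero cultures) when defined,
# else a median-based guess (robust to jackpot cultures), roughly corrected
# for dilution.
.ld_m_start <- function(cultures) {
  k <- cultures$counts
  z <- cultures$plating_fraction
  f0 <- mean(k == 0)
  m0 <- if (f0 > 0 && f0 < 1) -log(f0) else (median(k) + 1) / z
  max(m0, 1e-4)
}

#' Maximum-likelihood estimate of mutations per culture
#'
#' Maximizes the Lea-Coulson log-likelihood over m on the log scale
#' (bracketed golden-section search started at the P0 estimator), and
#' converts to the per-cell-division phenotypic rate `rate = m_hat / Nt`.
#'
#' @param cultures A [culture_set()].
#' @return A `rate_estimate` with `m_hat` and `rate` populated
#'   (confidence intervals are added by [estimate_rate()]).
#' @seealso [lr_interval()], [estimate_rate()]
#' @export
mle_m <- function(cultures) {
  stopifnot(inherits(cultures, "culture_set"))
  k <- cultures$counts
  if (all(k == 0)) {
    return(.rate_estimate(0, NULL, cultures))
  }
  m0 <- .ld_m_start(cultures)
  nll <- function(lm) -log_likelihood(cultures, exp(lm))
  lo <- log(m0) - 10
  hi <- log(m0) + 10
  for (attempt in 1:4) {
    opt <- optimize(nll, interval = c(lo, hi), tol = 1e-9)
    margin <- 1e-3
    if (opt$minimum > lo + margin && opt$minimum < hi - margin) {
      return(.rate_estimate(exp(opt$minimum), NULL, cultures))
    }
    if (opt$minimum <= lo + margin) lo <- lo - 10 else hi <- hi + 10
  }
  stop(sprintf(
    "mle_m did not converge: optimum stuck at search boundary (log m in [%.2f, %.2f], last value %.4f)",
    lo, hi, opt$minimum))
}

.rate_estimate <- function(m_hat, ci_m, cultures, level = NA_real_) {
  nt <- cultures$n_total
  structure(
    list(m_hat = m_hat,
         ci_m = ci_m,
         rate = m_hat / nt,
         ci_rate = if (is.null(ci_m)) NULL else ci_m / nt,
         n_total = nt,
         level = level,
         label = cultures$label),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s\n", if (nzchar(x$label)) x$label else "(unlabeled)"))
  cat(sprintf("  m_hat = %.4g", x$m_hat))
  if (!is.null(x$ci_m))
    cat(sprintf("  [%.4g, %.4g] (%d%% LR interval)",
                x$ci_m[1], x$ci_m[2], round(100 * x$level)))
  cat("\n")
  cat(sprintf("  rate  = %.4g per cell division", x$rate))
  if (!is.null(x$ci_rate))
    cat(sprintf("  [%.4g, %.4g]", x$ci_rate[1], x$ci_rate[2]))
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio confidence interval for m
#'
#' Endpoints solve \eqn{2[\ell(\hat m) - \ell(m)] = \chi^2_1(level)}
#' (3.841 at level 0.95), found by bisection on each side of the MLE.
#' The lower endpoint is 0 when the likelihood at the zero boundary is
#' within the cutoff (e.g. all-zero counts).
#'
#' @param cultures A [culture_set()].
#' @param level Confidence level in (0, 1); default 0.95.
#' @param m_hat Optional precomputed MLE (recomputed if missing).
#' @return Numeric vector `c(lo, hi)`.
#' @export
lr_interval <- function(cultures, level = 0.95, m_hat = NULL) {
  stopifnot(inherits(cultures, "culture_set"))
  if (!is.finite(level) || level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (is.null(m_hat)) m_hat <- mle_m(cultures)$m_hat
  half_crit <- qchisq(level, df = 1) / 2
  ll_hat <- log_likelihood(cultures, m_hat)
  f <- function(m) log_likelihood(cultures, m) - (ll_hat - half_crit)

  # lower endpoint
  if (m_hat == 0) {
    lo <- 0
  } else {
    tiny <- m_hat * 1e-10
    if (f(tiny) >= 0 || log_likelihood(cultures, 0) >= ll_hat - half_crit) {
      lo <- 0
    } else {
      r <- uniroot(function(lm) f(exp(lm)), lower = log(tiny), upper = log(m_hat),
                   tol = 1e-10)
      lo <- exp(r$root)
    }
  }

  # upper endpoint: expand a bracket by doubling, capped
  hi0 <- max(m_hat, .ld_m_start(cultures), 0.5)
  hi1 <- hi0 * 2
  iter <- 0
  while (f(hi1) > 0) {
    hi1 <- hi1 * 2
    iter <- iter + 1
    if (iter > 60) stop("lr_interval: upper endpoint not bracketed below search cap")
  }
  r <- uniroot(function(lm) f(exp(lm)), lower = log(max(m_hat, 1e-12)),
               upper = log(hi1), tol = 1e-10)
  hi <- exp(r$root)
  c(lo, hi)
}

#' Estimate a mutation rate from a fluctuation experiment
#'
#' Convenience wrapper: maximum-likelihood m, likelihood-ratio interval, and
#' conversion to the per-cell-division phenotypic rate and its interval
#' (both scaled by 1/Nt).
#'
#' @inheritParams lr_interval
#' @return A `rate_estimate` with `m_hat`, `ci_m`, `rate`, `ci_rate`.
#' @examples
#' cs <- culture_set(c(0, 0, 0, 1, 0, 2, 0, 0, 15), n_total = 2e6)
#' estimate_rate(cs)
#' @export
estimate_rate <- function(cultures, level = 0.95) {
  est <- mle_m(cultures)
  ci <- lr_interval(cultures, level = level, m_hat = est$m_hat)
  .rate_estimate(est$m_hat, ci, cultures, level = level)
}

#' Pool compatible fluctuation experiments
#'
#' Experiments whose total-division counts (Nt) all differ by less than
#' 2-fold (and that share a plating fraction) are combined for a single
#' rate estimate: counts are concatenated and the pooled Nt is the mean of
#' the member Nt values. Groups are formed greedily over Nt-sorted sets.
#' Sets that cannot be merged are returned separately and flagged
#' (attribute `flagged`) for independent estimation.
#'
#' @param sets List of [culture_set()] objects.
#' @return List of `culture_set` objects (possibly merged). When more than
#'   one group results, each carries attribute `flagged = TRUE`.
#' @export
pool_experiments <- function(sets) {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, logical(1), "culture_set")))
  ord <- order(vapply(sets, function(s) s$n_total, numeric(1)))
  sets <- sets[ord]
  groups <- list()
  current <- list(sets[[1]])
  for (s in sets[-1]) {
    nts <- vapply(current, function(x) x$n_total, numeric(1))
    same_z <- all(vapply(current, function(x) x$plating_fraction, numeric(1)) ==
                    s$plating_fraction)
    if (same_z && s$n_total / min(nts) < 2) {
      current <- c(current, list(s))
    } else {
      groups <- c(groups, list(current))
      current <- list(s)
    }
  }
  groups <- c(groups, list(current))
  out <- lapply(groups, function(g) {
    if (length(g) == 1) return(g[[1]])
    culture_set(
      counts = unlist(lapply(g, `[[`, "counts")),
      n_total = mean(vapply(g, `[[`, numeric(1), "n_total")),
      plating_fraction = g[[1]]$plating_fraction,
      label = paste(unique(vapply(g, `[[`, character(1), "label")), collapse = "+")
    )
  })
  if (length(out) > 1) out <- lapply(out, function(s) { attr(s, "flagged") <- TRUE; s })
  out
}
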