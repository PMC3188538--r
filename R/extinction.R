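# Branching-process model of error-induced extinction: each cell division
# hands every daughter a Poisson number of inactivating hits in essential
# genes; a hit daughter arrests (persists but never divides). Colony
# formation is a Galton-Watson process with offspring ~ Binomial(2, s),
# s = exp(-f*G*mu).

#' Genome model for the extinction simulator
#'
#' @param n_genes Number of genes G (default 6000, budding yeast).
#' @param essential_fraction Fraction f of genes essential for haploid
#'   viability (default 1/6).
#' @param per_gene_rate Inactivating mutations per gene per cell division
#'   (mu; assumes a typical reporter gene is representative).
#' @param visibility_threshold Cells constituting a visible colony
#'   (default 1e5, the plating scale at which no colonies were seen for
#'   extinct genotypes).
#' @param max_divisions Simulation horizon in generations.
#' @return A `genome_model` object.
#' @export
genome_model <- function(n_genes = 6000, essential_fraction = 1 / 6,
                         per_gene_rate = 0, visibility_threshold = 1e5,
                         max_divisions = 1000) {
  stopifnot(n_genes >= 1, essential_fraction > 0, essential_fraction <= 1,
            n_genes * essential_fraction >= 1,
            per_gene_rate >= 0, visibility_threshold >= 1, max_divisions >= 1)
  structure(list(n_genes = n_genes, essential_fraction = essential_fraction,
                 per_gene_rate = per_gene_rate,
                 visibility_threshold = visibility_threshold,
                 max_divisions = max_divisions),
            class = "genome_model")
}

#' Expected gene inactivations per cell division
#'
#' With G genes mutating at mu inactivating mutations per gene per
#' division, a daughter cell expects G*mu inactivations genome-wide and
#' f*G*mu in essential genes.
#'
#' @param model A [genome_model()].
#' @return Named vector `c(total = G*mu, essential = f*G*mu)`.
#' @examples
#' expected_inactivations(genome_model(per_gene_rate = 1e-3))  # ~6 genes
#' @export
expected_inactivations <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  tot <- model$n_genes * model$per_gene_rate
  c(total = tot, essential = model$essential_fraction * tot)
}

# exact zero-truncated Poisson draws by inversion
.rztpois <- function(n, lambda) {
  if (n == 0) return(integer(0))
  qpois(runif(n, min = ppois(0, lambda), max = 1), lambda)
}

#' Simulate colony formation under lethal mutation load
#'
#' Starts from one dividing founder. Each generation, every dividing cell
#' is replaced by two daughters; each daughter independently acquires
#' Poisson(f*G*mu) inactivating hits in essential genes and arrests if it
#' receives any (arrested cells persist and count toward colony size but
#' never divide). The simulation stops when total cells reach the
#' visibility threshold, when no dividing cells remain, or at the horizon.
#'
#' @param model A [genome_model()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `colony_outcome` list: `reached_visibility`, `final_cells`,
#'   `divisions_elapsed`, `lethal_hits_total`, `arrested_cells`.
#' @export
simulate_colony <- function(model, seed = NULL) {
  stopifnot(inherits(model, "genome_model"))
  if (!is.null(seed)) set.seed(seed)
  lambda <- model$essential_fraction * model$n_genes * model$per_gene_rate
  s <- exp(-lambda)
  dividing <- 1
  arrested <- 0
  hits <- 0
  gen <- 0
  while (dividing > 0 &&
         dividing + arrested < model$visibility_threshold &&
         gen < model$max_divisions) {
    births <- 2 * dividing
    surv <- rbinom(1, births, s)
    n_arr <- births - surv
    if (n_arr > 0) hits <- hits + sum(.rztpois(n_arr, lambda))
    arrested <- arrested + n_arr
    dividing <- surv
    gen <- gen + 1
  }
  structure(list(reached_visibility = dividing + arrested >= model$visibility_threshold,
                 final_cells = dividing + arrested,
                 divisions_elapsed = gen,
                 lethal_hits_total = hits,
                 arrested_cells = arrested),
            class = "colony_outcome")
}

#' Simulate many colonies
#'
#' @param model A [genome_model()].
#' @param reps Number of independent colonies.
#' @param seed Integer seed (one stream for the whole batch).
#' @return Data frame, one row per colony.
#' @export
simulate_colonies <- function(model, reps, seed = NULL) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(reps), function(i) {
    o <- simulate_colony(model)
    data.frame(rep = i, reached_visibility = o$reached_visibility,
               final_cells = o$final_cells,
               divisions_elapsed = o$divisions_elapsed,
               lethal_hits_total = o$lethal_hits_total)
  })
  do.call(rbind, rows)
}

#' Analytic Galton-Watson survival probability
#'
#' Closed-form oracle for the simulator: with per-daughter survival
#' probability \eqn{s = e^{-fG\mu}}, the extinction probability of the
#' dividing lineage is the smallest root in \[0, 1\] of
#' \eqn{q = (1 - s + sq)^2}; survival is \eqn{1 - q} (zero at and below
#' the critical point s = 1/2, i.e. \eqn{\mu \ge \ln 2 / (fG)}).
#'
#' @param model A [genome_model()].
#' @return Survival probability in \[0, 1\].
#' @export
gw_survival_analytic <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  lambda <- model$essential_fraction * model$n_genes * model$per_gene_rate
  s <- exp(-lambda)
  if (s <= 0.5) return(0)
  a <- s^2
  b <- 2 * s * (1 - s) - 1
  cc <- (1 - s)^2
  q <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  1 - min(max(q, 0), 1)
}

#' Critical per-gene mutation rate
#'
#' Bisection on mu for the simulated colony-survival probability crossing
#' `cutoff` (default 1%), i.e. the simulator's estimate of the maximal
#' mutation rate compatible with visible colony formation. The analytic
#' criterion is \eqn{\mu^* = \ln 2 / (fG)}; the Monte-Carlo estimate must
#' agree with it up to sampling error and the finite visibility horizon.
#'
#' @param model A [genome_model()] (its `per_gene_rate` is ignored).
#' @param reps Colonies per bisection point (>= 100).
#' @param seed Integer seed.
#' @param cutoff Survival probability defining "colonies still form".
#' @param mu_max Search cap; if survival still exceeds `cutoff` there,
#'   `Inf` is returned with a warning (no lethal targets regime).
#' @param iterations Bisection iterations.
#' @return Estimated critical rate (mutations per gene per division), with
#'   attribute `analytic` = ln 2/(fG).
#' @export
critical_rate <- function(model, reps = 200, seed = NULL, cutoff = 0.01,
                          mu_max = NULL, iterations = 12) {
  stopifnot(inherits(model, "genome_model"), reps >= 100,
            cutoff > 0, cutoff < 1)
  if (!is.null(seed)) set.seed(seed)
  fg <- model$essential_fraction * model$n_genes
  analytic <- log(2) / fg
  lo <- analytic / 10
  hi <- if (is.null(mu_max)) 4 * analytic else mu_max
  surv_hat <- function(mu) {
    m <- model
    m$per_gene_rate <- mu
    mean(vapply(seq_len(reps), function(i) simulate_colony(m)$reached_visibility,
                logical(1)))
  }
  if (surv_hat(lo) <= cutoff)
    stop("critical_rate: survival already below cutoff at the lower search bound")
  if (surv_hat(hi) > cutoff) {
    warning("critical_rate: survival above cutoff at the search cap; no finite estimate")
    return(structure(Inf, analytic = analytic))
  }
  for (it in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (surv_hat(mid) > cutoff) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, analytic = analytic)
}
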