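# Seeded generators of synthetic inputs with the statistical structure the
# estimators assume: Lea-Coulson fluctuation-assay counts (jackpots,
# plating dilution) and single-event mutant spectra on a coding reference.

#' Design of a synthetic fluctuation experiment
#'
#' Defaults mirror a 96-well reporter-gene protocol: 100 founder cells
#' per culture grown to ~2e6 cells. Use `n_cultures = 9` with dilution for
#' a colony-resuspension style assay.
#'
#' @param n_cultures Parallel cultures.
#' @param n0 Founder cells per culture (>= 1).
#' @param n_final Final cells per culture (Nt); must exceed `n0`.
#' @param mutation_rate Per-division mutation rate mu of the reporter.
#' @param plating_fraction Fraction of each culture plated, in (0, 1].
#' @param seed Optional integer seed.
#' @return A `fluctuation_design` object. The implied Lea-Coulson
#'   parameter is `m = mutation_rate * (n_final - n0)`.
#' @export
fluctuation_design <- function(n_cultures = 12, n0 = 100, n_final = 2e6,
                               mutation_rate = 1e-7, plating_fraction = 1,
                               seed = NULL) {
  stopifnot(n_cultures >= 1, n0 >= 1, n_final > n0,
            mutation_rate >= 0, plating_fraction > 0, plating_fraction <= 1)
  structure(list(n_cultures = as.integer(n_cultures), n0 = n0, n_final = n_final,
                 mutation_rate = mutation_rate, plating_fraction = plating_fraction,
                 seed = seed),
            class = "fluctuation_design")
}

#' Design with a target Lea-Coulson m
#'
#' Convenience wrapper fixing `mutation_rate = m / (n_final - n0)`.
#'
#' @param m Expected mutation events per culture.
#' @param ... Passed to [fluctuation_design()].
#' @inheritParams fluctuation_design
#' @export
fluctuation_design_m <- function(m, n_cultures = 9, n0 = 1, n_final = 1e9,
                                 plating_fraction = 1, seed = NULL, ...) {
  fluctuation_design(n_cultures = n_cultures, n0 = n0, n_final = n_final,
                     mutation_rate = m / (n_final - n0),
                     plating_fraction = plating_fraction, seed = seed, ...)
}

#' Simulate mutant counts of parallel cultures
#'
#' Mutations arise uniformly over the `n_final - n0` cell divisions of
#' exponential growth; a mutation arising when the population has n cells
#' founds a resistant clone of final size ~ n_final/n. Under exponential
#' growth this clone-size distribution is P(size = j) = 1/(j(j+1))
#' (sampled as `floor(1/U)`, capped at the culture size), the Lea-Coulson
#' form the estimator assumes. Observed counts are binomially thinned at
#' the plating fraction.
#'
#' @param design A [fluctuation_design()].
#' @return A [culture_set()] with `n_total = n_final` (divisions inferred
#'   from final colony-forming units).
#' @export
simulate_cultures <- function(design) {
  stopifnot(inherits(design, "fluctuation_design"))
  if (design$mutation_rate * design$n_final > 1e3)
    stop("mutation_rate * n_final > 1000: expected mutant load too large (jackpot overflow)")
  if (!is.null(design$seed)) set.seed(design$seed)
  m <- design$mutation_rate * (design$n_final - design$n0)
  counts <- vapply(seq_len(design$n_cultures), function(i) {
    n_mut <- rpois(1, m)
    if (n_mut == 0) return(0L)
    sizes <- pmin(floor(1 / runif(n_mut)), design$n_final)
    total <- sum(sizes)
    as.integer(rbinom(1, size = min(total, .Machine$integer.max), design$plating_fraction))
  }, integer(1))
  culture_set(counts, n_total = design$n_final,
              plating_fraction = design$plating_fraction,
              label = sprintf("synthetic m=%.3g", m))
}

.stop_reachable_sites <- function(cds) {
  # enumerate all (position, alt) substitutions and their effects
  n <- nchar(cds)
  ref <- strsplit(cds, "")[[1]]
  pos <- rep(seq_len(n), each = 4)
  alt <- rep(c("A", "C", "G", "T"), times = n)
  keep <- ref[pos] != alt
  pos <- pos[keep]; alt <- alt[keep]
  eff <- vapply(seq_along(pos), function(i) classify_substitution(cds, pos[i], alt[i]),
                character(1))
  data.frame(position = pos, alt = alt, effect = eff, stringsAsFactors = FALSE)
}

#' Simulate a mutant spectrum
#'
#' Generates `n_clones` mutant sequences, each carrying one mutation event
#' sampled from the requested category proportions (sites uniform over the
#' positions compatible with the requested effect), together with a truth
#' table of the planted events. [diff_sequences()] plus [tally_spectrum()]
#' on the output recovers the truth tallies exactly.
#'
#' Categories: `chain_terminating` and `missense` substitutions, `indel`
#' (single-base insertion or deletion, equiprobable), and `complex`
#' (two-base deletion).
#'
#' @param n_clones Number of mutant clones (>= 0).
#' @param proportions Numeric vector of length 4 summing to 1:
#'   (chain_terminating, missense, indel, complex).
#' @param cds Reference coding sequence (length a multiple of 3).
#' @param seed Optional integer seed.
#' @param exact_counts Optional named integer vector
#'   (`chain_terminating`, `missense`, `indel`, `complex`) fixing the
#'   category counts exactly instead of multinomial sampling;
#'   overrides `n_clones`/`proportions`.
#' @return List with `mutants` (named character vector of sequences) and
#'   `truth` (data frame: clone_id, position, ref, alt, kind, effect).
#' @export
simulate_spectrum <- function(n_clones, proportions = c(0.2, 0.7, 0.08, 0.02),
                              cds, seed = NULL, exact_counts = NULL) {
  cds <- .check_dna(cds, "cds")
  stopifnot(nchar(cds) %% 3 == 0)
  if (!is.null(seed)) set.seed(seed)
  cats <- c("chain_terminating", "missense", "indel", "complex")
  if (is.null(exact_counts)) {
    stopifnot(n_clones >= 0, length(proportions) == 4,
              abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0))
    drawn <- if (n_clones == 0) character(0)
             else sample(cats, n_clones, replace = TRUE, prob = proportions)
  } else {
    stopifnot(all(names(exact_counts) %in% cats), all(exact_counts >= 0))
    full <- setNames(rep(0L, 4), cats)
    full[names(exact_counts)] <- as.integer(exact_counts)
    drawn <- sample(rep(cats, times = full))
  }
  n <- length(drawn)
  empty_truth <- data.frame(clone_id = character(), position = integer(),
                            ref = character(), alt = character(),
                            kind = character(), effect = character(),
                            stringsAsFactors = FALSE)
  if (n == 0) return(list(mutants = character(0), truth = empty_truth))

  sites <- .stop_reachable_sites(cds)
  ct_sites <- sites[sites$effect == "chain_terminating", ]
  mis_sites <- sites[sites$effect == "missense", ]
  if (any(drawn == "chain_terminating") && nrow(ct_sites) == 0)
    stop("no chain-terminating substitution is reachable in this cds")
  if (any(drawn == "missense") && nrow(mis_sites) == 0)
    stop("no missense substitution is reachable in this cds")

  L <- nchar(cds)
  ref_chars <- strsplit(cds, "")[[1]]
  mutants <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("clone_%04d", i)
    kind <- drawn[i]
    rec <- switch(kind,
      chain_terminating = ,
      missense = {
        tab <- if (kind == "chain_terminating") ct_sites else mis_sites
        j <- sample.int(nrow(tab), 1)
        data.frame(position = tab$position[j], ref = ref_chars[tab$position[j]],
                   alt = tab$alt[j], kind = "substitution", effect = tab$effect[j],
                   stringsAsFactors = FALSE)
      },
      indel = {
        if (runif(1) < 0.5) {
          p <- sample.int(L, 1)
          data.frame(position = p, ref = ref_chars[p], alt = "-",
                     kind = "deletion", effect = NA_character_,
                     stringsAsFactors = FALSE)
        } else {
          p <- sample.int(L, 1)
          data.frame(position = p, ref = "-", alt = sample(c("A", "C", "G", "T"), 1),
                     kind = "insertion", effect = NA_character_,
                     stringsAsFactors = FALSE)
        }
      },
      complex = {
        p <- sample.int(L - 1, 1)
        data.frame(position = p, ref = paste0(ref_chars[p], ref_chars[p + 1]),
                   alt = "", kind = "complex", effect = NA_character_,
                   stringsAsFactors = FALSE)
      })
    mutants[i] <- apply_mutation(cds, rec)
    truth[[i]] <- cbind(clone_id = id, rec, stringsAsFactors = FALSE)
  }
  names(mutants) <- sprintf("clone_%04d", seq_len(n))
  list(mutants = mutants, truth = do.call(rbind, truth))
}

#' Generate a random open reading frame
#'
#' ATG start, internal codons drawn uniformly from the 60 non-stop
#' non-ATG-reserved codons, TAA stop. Deterministic given `seed`.
#'
#' @param n_codons Total codons including start and stop (>= 3).
#' @param seed Optional integer seed.
#' @return Character string of length `3 * n_codons`.
#' @export
random_orf <- function(n_codons, seed = NULL) {
  stopifnot(n_codons >= 3)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  internal <- setdiff(codons, .STOP_CODONS)
  body <- sample(internal, n_codons - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Bundled synthetic reporter ORF
#'
#' A 1773-bp synthetic open reading frame (591 codons) standing in for a
#' CAN1-sized resistance reporter; generated once by [random_orf()] with a
#' fixed seed and shipped as a plain-text FASTA fixture. No real genomic
#' sequence is required anywhere in the package.
#'
#' @return Character string of length 1773.
#' @export
synthetic_reporter_orf <- function() {
  path <- system.file("extdata", "synthetic_reporter_orf.fa", package = "mutfidelity")
  as.character(read_fasta(path)[[1]])
}
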