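# Per-base-pair rate conversion (Drake-style corrections for phenotypically
# silent substitutions), repair-pathway efficiency arithmetic, predicted
# double-mutant rates, growth grading, and the cross-organism table.

#' Define a mutation-reporter target locus
#'
#' @param name Locus name.
#' @param T Target length in base pairs (> 0).
#' @param intrinsic_adjust Cross-locus rate multiplier applied when
#'   comparing loci with different intrinsic rates (default 1; e.g. 1.8 to
#'   place URA3-derived rates on the CAN1 scale).
#' @return A `target_locus` object.
#' @export
target_locus <- function(name, T, intrinsic_adjust = 1) {
  stopifnot(is.finite(T), T > 0, is.finite(intrinsic_adjust), intrinsic_adjust > 0)
  structure(list(name = as.character(name), T = as.numeric(T),
                 intrinsic_adjust = as.numeric(intrinsic_adjust)),
            class = "target_locus")
}

#' Correction factors for undetected mutations
#'
#' A resistance reporter only reveals mutations that inactivate the protein,
#' so the observed spectrum under-counts substitutions. Chain-terminating
#' changes (3 of the 64 codons) are assumed fully detectable, anchoring the
#' correction: the substitution-only factor is
#' \deqn{C = (64/3)\, B_{CT} / B,}
#' and the combined substitution+indel factor is
#' \deqn{C'' = [(64/3)\, B_{CT} + I] / M.}
#' The effective target size is \eqn{\tau = T / C''}: the number of base
#' pairs at which every mutation would score. These forms reproduce the
#' published reference values for the standard yeast and diploid reporters
#' (e.g. C = 4.87 and tau = 391 bp for a 1773-bp target with
#' B = 442, B_CT = 101, I = 42, M = 484).
#'
#' @param counts A [spectrum_counts()] with `B_CT > 0`.
#' @param locus A [target_locus()].
#' @return A `correction_factors` object with fields `C`, `C2` (the
#'   combined factor C''), and `tau`.
#' @export
correction_factors <- function(counts, locus) {
  stopifnot(inherits(counts, "spectrum_counts"), inherits(locus, "target_locus"))
  if (counts$M <= 0) stop("no mutants: M must be > 0")
  if (counts$B_CT == 0)
    stop("correction undefined: no chain-terminating substitutions observed (B_CT = 0)")
  C <- (64 / 3) * counts$B_CT / counts$B
  C2 <- ((64 / 3) * counts$B_CT + counts$I) / counts$M
  structure(list(C = C, C2 = C2, tau = locus$T / C2, locus = locus),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("<correction_factors> %s (T = %g bp): C = %.3g, C'' = %.3g, tau = %.4g bp\n",
              x$locus$name, x$locus$T, x$C, x$C2, x$tau))
  invisible(x)
}

#' Convert a phenotypic rate to a per-base-pair rate
#'
#' \eqn{\mu_b = \mu_T \cdot C'' / T}, or \eqn{\mu_b = \mu_T / \tau} when an
#' effective target size is supplied directly (e.g. a codon-enumerated
#' target where no spectrum correction applies). Any cross-locus
#' `intrinsic_adjust` on the locus is *not* applied here; see
#' [robustness_table()].
#'
#' @param mu_T Phenotypic mutation rate (mutants per cell division), >= 0.
#' @param factors A [correction_factors()] (ignored when `tau` is given).
#' @param tau Effective target size in bp, for direct conversion.
#' @return Per-base-pair mutation rate.
#' @examples
#' per_bp_rate(65e-7, tau = 20)  # codon-enumerated target
#' @export
per_bp_rate <- function(mu_T, factors = NULL, tau = NULL) {
  stopifnot(is.finite(mu_T), mu_T >= 0)
  if (!is.null(tau)) {
    stopifnot(is.finite(tau), tau > 0)
    return(mu_T / tau)
  }
  stopifnot(inherits(factors, "correction_factors"))
  mu_T * factors$C2 / factors$locus$T
}

#' Effective target size from enumerated mutable sites
#'
#' For targets where resistance arises only at known codons, the effective
#' target size is base pairs per allele times allele number (e.g. 5 bp x 4
#' alleles = 20 bp for a tetraploid cell line).
#'
#' @param bp_per_allele Mutable base pairs per allele (> 0).
#' @param n_alleles Number of alleles (positive integer).
#' @return tau in base pairs.
#' @export
allele_target_size <- function(bp_per_allele, n_alleles) {
  stopifnot(is.finite(bp_per_allele), bp_per_allele > 0,
            n_alleles > 0, n_alleles == floor(n_alleles))
  bp_per_allele * n_alleles
}

#' Fold effect of a repair deficiency
#'
#' Ratio of the mutation rate of a repair-deficient strain to the matched
#' proficient strain.
#'
#' @param rate_deficient,rate_proficient Phenotypic rates; the proficient
#'   rate must be > 0.
#' @return The fold increase (reported to 3 significant figures in tables).
#' @export
fold_effect <- function(rate_deficient, rate_proficient) {
  stopifnot(is.finite(rate_deficient), rate_deficient >= 0)
  if (!is.finite(rate_proficient) || rate_proficient <= 0)
    stop("rate_proficient must be > 0")
  rate_deficient / rate_proficient
}

#' Repair-pathway efficiency from a fold effect
#'
#' If removing a repair pathway raises the mutation rate F-fold, the
#' pathway corrected a fraction \eqn{1 - 1/F} of the errors reaching it:
#' efficiency (%) = \eqn{100\,(1 - 1/F)}. A fold below 1 (an antimutator
#' input) yields a negative efficiency with a warning.
#'
#' @param fold Rate ratio deficient/proficient.
#' @return A `repair_efficiency` object with `fold` and `efficiency_pct`.
#' @examples
#' repair_efficiency(157)  # > 99% of errors corrected
#' @export
repair_efficiency <- function(fold) {
  stopifnot(is.finite(fold), fold > 0)
  if (fold < 1)
    warning("fold < 1: antimutator input, efficiency reported as negative")
  structure(list(fold = fold, efficiency_pct = 100 * (1 - 1 / fold)),
            class = "repair_efficiency")
}

#' @export
print.repair_efficiency <- function(x, ...) {
  cat(sprintf("<repair_efficiency> fold = %.4g -> %.4g%% of errors corrected\n",
              x$fold, x$efficiency_pct))
  invisible(x)
}

#' Combined fidelity of serial repair pathways
#'
#' Pathways acting in series on the same error stream multiply: the
#' combined fold contribution of proofreading and mismatch repair is the
#' product of their individual folds.
#'
#' @param fold_mmr,fold_exo Individual fold effects (>= 1).
#' @return The combined fold.
#' @export
combined_fidelity <- function(fold_mmr, fold_exo) {
  stopifnot(is.finite(fold_mmr), fold_mmr >= 1, is.finite(fold_exo), fold_exo >= 1)
  fold_mmr * fold_exo
}

#' Predict the rate of an unconstructable double mutant
#'
#' Rate of the single (repair-proficient) mutant times the average fold
#' effect of the missing pathway.
#'
#' @param rate_single Measured single-mutant rate (> 0).
#' @param avg_fold Average fold effect (> 0).
#' @return Predicted phenotypic rate.
#' @export
predict_double_mutant_rate <- function(rate_single, avg_fold) {
  stopifnot(is.finite(rate_single), rate_single > 0,
            is.finite(avg_fold), avg_fold > 0)
  rate_single * avg_fold
}

#' Grade colony-forming capacity from the mutation rate
#'
#' Semi-quantitative growth grades keyed to the phenotypic mutation rate:
#' wild-type growth (`+++`) up to 5e-5 mutants per cell division, slow
#' growth (`++`) up to 1e-3, severe deficit (`+`) up to 2e-3, and failure
#' to form visible colonies (`-`) beyond. Bands are configurable; defaults
#' reflect observed growth of haploid yeast mutator panels.
#'
#' @param rate Phenotypic mutation rate(s), >= 0.
#' @param thresholds Named numeric vector with band edges `wt_max`,
#'   `slow_max`, `severe_max` (increasing).
#' @return Character vector of grades in `{+++, ++, +, -}`.
#' @export
classify_growth <- function(rate,
                            thresholds = c(wt_max = 5e-5, slow_max = 1e-3,
                                           severe_max = 2e-3)) {
  stopifnot(all(is.finite(rate)), all(rate >= 0),
            all(c("wt_max", "slow_max", "severe_max") %in% names(thresholds)),
            !is.unsorted(thresholds[c("wt_max", "slow_max", "severe_max")]))
  ifelse(rate <= thresholds[["wt_max"]], "+++",
    ifelse(rate < thresholds[["slow_max"]], "++",
      ifelse(rate < thresholds[["severe_max"]], "+", "-")))
}

#' Bundled locus conversion presets
#'
#' Conversion constants for the reporters used in cross-organism
#' comparisons: the haploid yeast CAN1-style reporter (spectrum-derived
#' correction), the diploid yeast URA3 reporter (external spectrum
#' constants, with a 1.8x cross-locus adjustment), and the mouse
#' ouabain-resistance target (codon-enumerated tau = 5 bp x 4 alleles).
#'
#' @return Named list of presets; each has `mode` (`"drake"` or
#'   `"target_size"`) and its constants.
#' @export
locus_presets <- function() {
  path <- system.file("extdata", "locus_presets.json", package = "mutfidelity")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Cross-organism per-base-pair rate table
#'
#' Converts phenotypic rates to per-base-pair rates using named presets
#' (or explicit constants) and grades growth capacity, assembling the
#' comparison table of mutational robustness across organisms.
#'
#' @param entries Data frame with columns `organism`, `mu_T`, and `preset`
#'   (a name from [locus_presets()]); alternatively columns `C2`, `T`
#'   and/or `tau`, `adjust` to supply constants explicitly.
#' @return Data frame with `organism`, `mu_T`, `mu_b` (unadjusted),
#'   `mu_b_adjusted` (cross-locus adjustment applied), and `grade`.
#' @export
robustness_table <- function(entries) {
  stopifnot(is.data.frame(entries))
  out <- data.frame(organism = character(), mu_T = numeric(), mu_b = numeric(),
                    mu_b_adjusted = numeric(), grade = character(),
                    stringsAsFactors = FALSE)
  if (nrow(entries) == 0) return(out)
  stopifnot(all(c("organism", "mu_T") %in% names(entries)))
  presets <- locus_presets()
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, , drop = FALSE]
    cons <- if ("preset" %in% names(e) && !is.na(e$preset)) {
      if (!e$preset %in% names(presets)) stop("unknown preset: ", e$preset)
      presets[[e$preset]]
    } else {
      as.list(e)
    }
    adjust <- if (!is.null(cons$adjust)) cons$adjust else 1
    mu_b <- if (identical(cons$mode, "target_size") ||
                (is.null(cons$C2) && !is.null(cons$tau))) {
      if (is.null(cons$tau)) stop("entry ", i, ": missing tau")
      per_bp_rate(e$mu_T, tau = cons$tau)
    } else {
      if (is.null(cons$C2) || is.null(cons$T)) stop("entry ", i, ": missing C2 or T")
      e$mu_T * cons$C2 / cons$T
    }
    out <- rbind(out, data.frame(
      organism = e$organism, mu_T = e$mu_T, mu_b = mu_b,
      mu_b_adjusted = mu_b * adjust, grade = classify_growth(e$mu_T),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
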