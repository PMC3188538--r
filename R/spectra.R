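# Mutation-spectrum classification against a coding reference: effect of a
# base substitution (chain-terminating / missense / silent), sequence
# diffing, and the tallies that feed the per-base-pair correction.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.check_dna <- function(x, what = "sequence") {
  if (!is.character(x)) x <- as.character(x)  # DNAString etc.
  x <- toupper(x)
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0)
    stop(sprintf("%s contains a non-ACGT character at position %d", what, bad))
  x
}

#' Classify the effect of a base substitution in a coding sequence
#'
#' A substitution is chain-terminating if the mutated codon is one of
#' TAA/TAG/TGA, silent if the encoded amino acid is unchanged (standard
#' nuclear genetic code), and missense otherwise. Positions are 1-based on
#' the coding strand.
#'
#' @param cds Coding sequence (character or `DNAString`); length must be a
#'   multiple of 3.
#' @param position 1-based position of the substituted base.
#' @param alt_base Replacement base, one of A/C/G/T, different from the
#'   reference base.
#' @return One of `"chain_terminating"`, `"silent"`, `"missense"`.
#' @examples
#' classify_substitution("ATGTGGTAA", 6, "A")  # TGG -> TGA, chain_terminating
#' @export
classify_substitution <- function(cds, position, alt_base) {
  cds <- .check_dna(cds, "cds")
  n <- nchar(cds)
  if (n %% 3 != 0) stop("cds length must be divisible by 3")
  if (position < 1 || position > n || position != floor(position))
    stop("position must be a 1-based index into the cds")
  alt_base <- toupper(alt_base)
  if (!alt_base %in% c("A", "C", "G", "T")) stop("alt_base must be one of A/C/G/T")
  ref_base <- substr(cds, position, position)
  if (ref_base == alt_base) stop("alt_base equals the reference base")
  codon_start <- 3 * ((position - 1) %/% 3) + 1
  ref_codon <- substr(cds, codon_start, codon_start + 2)
  mut_codon <- ref_codon
  substr(mut_codon, position - codon_start + 1, position - codon_start + 1) <- alt_base
  if (mut_codon %in% .STOP_CODONS) return("chain_terminating")
  gc <- Biostrings::GENETIC_CODE
  if (gc[[ref_codon]] == gc[[mut_codon]]) "silent" else "missense"
}

.common_prefix_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Diff a mutant coding sequence against its reference
#'
#' Equal-length inputs are scanned per position for substitutions. Inputs
#' differing in length by one base are resolved to a single insertion or
#' deletion by end-anchored alignment (longest common prefix/suffix); the
#' reported position is the leftmost consistent placement. Any other
#' length difference, or an unresolvable single-base difference, yields one
#' `complex` record spanning the differing region.
#'
#' @param ref_cds,mutant_cds Sequences over A/C/G/T (character or
#'   `DNAString`). Ambiguity codes are rejected.
#' @param classify_effects Annotate substitution records with their coding
#'   effect via [classify_substitution()] (requires `ref_cds` length to be a
#'   multiple of 3).
#' @return A data frame of mutation records with columns `position`,
#'   `ref`, `alt`, `kind`, `effect`; zero rows for identical inputs.
#' @export
diff_sequences <- function(ref_cds, mutant_cds, classify_effects = TRUE) {
  ref <- .check_dna(ref_cds, "ref_cds")
  mut <- .check_dna(mutant_cds, "mutant_cds")
  r <- strsplit(ref, "")[[1]]
  m <- strsplit(mut, "")[[1]]
  empty <- data.frame(position = integer(), ref = character(), alt = character(),
                      kind = character(), effect = character(),
                      stringsAsFactors = FALSE)
  if (length(r) == length(m)) {
    pos <- which(r != m)
    if (length(pos) == 0) return(empty)
    eff <- rep(NA_character_, length(pos))
    if (classify_effects && length(r) %% 3 == 0) {
      eff <- vapply(seq_along(pos), function(i)
        classify_substitution(ref, pos[i], m[pos[i]]), character(1))
    }
    return(data.frame(position = pos, ref = r[pos], alt = m[pos],
                      kind = "substitution", effect = eff,
                      stringsAsFactors = FALSE))
  }
  delta <- length(m) - length(r)
  pre <- .common_prefix_len(r, m)
  suf <- .common_prefix_len(rev(r), rev(m))
  short_len <- min(length(r), length(m))
  if (abs(delta) == 1 && pre + suf >= short_len) {
    # deletion/insertion placements are ambiguous within a homopolymer run;
    # report the leftmost: walk back from pre+1 while the run continues
    if (delta == -1) {
      p <- pre + 1L
      while (p > 1L && r[p - 1L] == r[pre + 1L]) p <- p - 1L
      return(data.frame(position = p, ref = r[pre + 1L], alt = "-",
                        kind = "deletion", effect = NA_character_,
                        stringsAsFactors = FALSE))
    }
    p <- pre + 1L
    while (p > 1L && m[p - 1L] == m[pre + 1L]) p <- p - 1L
    return(data.frame(position = p, ref = "-", alt = m[pre + 1L],
                      kind = "insertion", effect = NA_character_,
                      stringsAsFactors = FALSE))
  }
  # multi-base / irregular event: single complex record over the region
  # between the anchored ends (prefix and suffix must not overlap)
  if (pre + suf > short_len) suf <- short_len - pre
  end_r <- length(r) - suf
  end_m <- length(m) - suf
  seg <- function(x, from, to) if (to < from) "" else paste(x[from:to], collapse = "")
  data.frame(position = pre + 1L,
             ref = seg(r, pre + 1L, end_r),
             alt = seg(m, pre + 1L, end_m),
             kind = "complex", effect = NA_character_,
             stringsAsFactors = FALSE)
}

#' Tally a mutation spectrum
#'
#' Aggregates per-clone mutation records into the counts used by the
#' per-base-pair correction: B (base substitutions, silent excluded),
#' B_CT (chain-terminating), B_mis (missense), I (insertions + deletions +
#' complex events), and M = B + I total scored events. Each event counts
#' once, so a clone carrying two mutations contributes two events. Silent
#' substitutions are undetectable in a resistance reporter; if present they
#' are excluded from B, counted in `silent`, and a warning is issued.
#'
#' @param records Data frame of mutation records (columns `kind` and
#'   `effect`, as produced by [diff_sequences()]; a `clone_id` column is
#'   allowed and ignored by the tally).
#' @return An object of class `spectrum_counts` with fields `B`, `B_CT`,
#'   `B_mis`, `I`, `M`, `silent`.
#' @export
tally_spectrum <- function(records) {
  stopifnot(is.data.frame(records), all(c("kind", "effect") %in% names(records)))
  kind <- records$kind
  ok <- kind %in% c("substitution", "insertion", "deletion", "complex")
  if (any(!ok)) stop("unknown record kind: ", paste(unique(kind[!ok]), collapse = ", "))
  sub <- records[kind == "substitution", , drop = FALSE]
  n_silent <- sum(sub$effect == "silent", na.rm = TRUE)
  if (n_silent > 0)
    warning(sprintf("%d silent substitution(s) excluded from B (undetectable in reporter)",
                    n_silent))
  b_ct <- sum(sub$effect == "chain_terminating", na.rm = TRUE)
  b_mis <- sum(sub$effect == "missense", na.rm = TRUE)
  i_n <- sum(kind %in% c("insertion", "deletion", "complex"))
  spectrum_counts(B_CT = b_ct, B_mis = b_mis, I = i_n, silent = n_silent)
}

#' Spectrum counts
#'
#' @param B_CT Chain-terminating substitution count.
#' @param B_mis Missense substitution count.
#' @param I Insertion + deletion + complex event count.
#' @param silent Silent substitutions observed (excluded from B).
#' @return `spectrum_counts` object with derived `B = B_CT + B_mis` and
#'   `M = B + I`.
#' @export
spectrum_counts <- function(B_CT, B_mis, I, silent = 0) {
  stopifnot(B_CT >= 0, B_mis >= 0, I >= 0, silent >= 0)
  structure(list(B = B_CT + B_mis, B_CT = B_CT, B_mis = B_mis,
                 I = I, M = B_CT + B_mis + I, silent = silent),
            class = "spectrum_counts")
}

#' @export
print.spectrum_counts <- function(x, ...) {
  cat(sprintf(
    "<spectrum_counts> M = %d events: B = %d substitutions (%d chain-terminating + %d missense), I = %d indel/complex",
    x$M, x$B, x$B_CT, x$B_mis, x$I))
  if (x$silent > 0) cat(sprintf(" [+%d silent excluded]", x$silent))
  cat("\n")
  invisible(x)
}

#' Apply a mutation record to a reference sequence
#'
#' Inverse of [diff_sequences()] for single events; used by the synthetic
#' generator and in round-trip checks.
#'
#' @param ref_cds Reference sequence.
#' @param record One-row data frame with `position`, `ref`, `alt`, `kind`.
#' @return The mutant sequence (character).
#' @export
apply_mutation <- function(ref_cds, record) {
  ref <- .check_dna(ref_cds, "ref_cds")
  stopifnot(is.data.frame(record), nrow(record) == 1)
  p <- record$position
  switch(record$kind,
    substitution = {
      out <- ref
      substr(out, p, p) <- record$alt
      out
    },
    deletion = paste0(substr(ref, 1, p - 1), substr(ref, p + 1, nchar(ref))),
    insertion = paste0(substr(ref, 1, p - 1), record$alt, substr(ref, p, nchar(ref))),
    complex = paste0(substr(ref, 1, p - 1), record$alt,
                     substr(ref, p + nchar(record$ref), nchar(ref))),
    stop("unknown record kind: ", record$kind)
  )
}
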