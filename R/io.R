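# File formats and the end-to-end pipeline: TSV readers/writers (tab
# separated, UTF-8, mandatory header, '#' comments), FASTA via Biostrings,
# locus presets, and the report bundle chaining rate -> fold -> per-bp ->
# grade.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write sequences to a FASTA file (60-column wrap)
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read fluctuation-assay counts
#'
#' TSV with one row per culture and mandatory header columns
#' `experiment_id`, `count`, `n_total`, `plating_fraction` ('#' comment
#' lines permitted). `n_total` and `plating_fraction` must be constant
#' within an experiment.
#'
#' @param path TSV file.
#' @return Named list of [culture_set()] objects, one per experiment.
#' @export
read_cultures_tsv <- function(path) {
  df <- .read_tsv(path)
  need <- c("experiment_id", "count", "n_total", "plating_fraction")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("counts TSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$count) | df$count < 0)
  if (length(bad) > 0)
    stop("invalid count at data line ", bad[1])
  split_df <- split(df, df$experiment_id)
  out <- lapply(names(split_df), function(id) {
    g <- split_df[[id]]
    if (length(unique(g$n_total)) != 1 || length(unique(g$plating_fraction)) != 1)
      stop("experiment ", id, ": n_total and plating_fraction must be constant")
    culture_set(g$count, n_total = g$n_total[1],
                plating_fraction = g$plating_fraction[1], label = id)
  })
  names(out) <- names(split_df)
  out
}

#' Write fluctuation-assay counts
#'
#' @param sets Named list of [culture_set()] objects.
#' @param path Output TSV.
#' @export
write_cultures_tsv <- function(sets, path) {
  if (inherits(sets, "culture_set")) sets <- list(sets)
  ids <- if (is.null(names(sets)) || any(!nzchar(names(sets))))
    vapply(sets, function(s) if (nzchar(s$label)) s$label else "exp", character(1))
  else names(sets)
  df <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    data.frame(experiment_id = ids[i], count = s$counts, n_total = s$n_total,
               plating_fraction = s$plating_fraction, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation-spectrum table
#'
#' TSV with header columns `clone_id`, `position`, `ref`, `alt`, `kind`,
#' `effect`.
#'
#' @param path TSV file.
#' @return Data frame of mutation records.
#' @export
read_spectrum_tsv <- function(path) {
  df <- .read_tsv(path)
  need <- c("clone_id", "position", "ref", "alt", "kind", "effect")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("spectrum TSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Write a mutation-spectrum table
#'
#' @param records Data frame of mutation records.
#' @param path Output TSV.
#' @export
write_spectrum_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param level Confidence level for likelihood-ratio intervals.
#' @param seed Seed governing any randomness downstream.
#' @param locus Name of a [locus_presets()] entry, or a [target_locus()].
#' @param rate_scale Rates in report tables are printed as value x
#'   10^-`rate_scale` (default 7) with `rate_digits` significant figures.
#' @param rate_digits Significant figures for printed rates.
#' @return A `pipeline_config` list, versioned and echoed into report
#'   headers.
#' @export
pipeline_config <- function(level = 0.95, seed = 1, locus = "haploid_yeast_reporter",
                            rate_scale = 7, rate_digits = 2) {
  stopifnot(level > 0, level < 1)
  structure(list(version = as.character(utils::packageVersion("mutfidelity")),
                 level = level, seed = seed, locus = locus,
                 rate_scale = rate_scale, rate_digits = rate_digits),
            class = "pipeline_config")
}

.config_header <- function(config) {
  locus_name <- if (inherits(config$locus, "target_locus")) config$locus$name
                else as.character(config$locus)
  c(sprintf("# mutfidelity %s", config$version),
    sprintf("# level=%g seed=%s locus=%s rate_scale=1e-%d",
            config$level, format(config$seed), locus_name, config$rate_scale))
}

.fmt_rate <- function(rate, config) {
  formatC(signif(rate * 10^config$rate_scale, config$rate_digits),
          format = "fg", flag = "")
}

.resolve_locus <- function(config) {
  if (inherits(config$locus, "target_locus")) return(config$locus)
  presets <- locus_presets()
  if (!config$locus %in% names(presets))
    stop("unknown locus preset: ", config$locus)
  p <- presets[[config$locus]]
  if (is.null(p$T)) stop("preset ", config$locus, " has no target length T")
  target_locus(config$locus, T = p$T,
               intrinsic_adjust = if (is.null(p$adjust)) 1 else p$adjust)
}

#' Run the full analysis pipeline
#'
#' Chains the stages: per-experiment maximum-likelihood rates with
#' likelihood-ratio intervals from a counts TSV; optional spectrum tally
#' and correction factors from a spectrum TSV; per-base-pair conversion of
#' each rate; and growth grading. Deterministic given config and inputs.
#'
#' @param counts_tsv Path to the fluctuation-counts TSV
#'   (see [read_cultures_tsv()]).
#' @param spectrum_tsv Optional path to a spectrum TSV
#'   (see [read_spectrum_tsv()]).
#' @param config A [pipeline_config()].
#' @param reference_experiment Optional experiment id; when given, a `fold`
#'   column (3 significant figures) reports each rate relative to it, as in
#'   repair-deficiency fold-effect tables.
#' @return A `pipeline_report` list: `header` (character), `rates`
#'   (data frame with formatted rate x 10^-7 columns), `spectrum`
#'   (spectrum_counts or NULL), `factors` (correction_factors or NULL),
#'   `per_bp` (data frame or NULL).
#' @export
run_pipeline <- function(counts_tsv, spectrum_tsv = NULL, config = pipeline_config(),
                         reference_experiment = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sets <- read_cultures_tsv(counts_tsv)
  ests <- lapply(sets, estimate_rate, level = config$level)
  rates <- do.call(rbind, lapply(names(ests), function(id) {
    e <- ests[[id]]
    data.frame(experiment_id = id,
               n_cultures = length(sets[[id]]$counts),
               m_hat = e$m_hat,
               rate = e$rate, rate_lo = e$ci_rate[1], rate_hi = e$ci_rate[2],
               rate_fmt = sprintf("%s (%s, %s)", .fmt_rate(e$rate, config),
                                  .fmt_rate(e$ci_rate[1], config),
                                  .fmt_rate(e$ci_rate[2], config)),
               grade = classify_growth(e$rate),
               stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL
  if (!is.null(reference_experiment)) {
    if (!reference_experiment %in% rates$experiment_id)
      stop("reference_experiment not found: ", reference_experiment)
    ref_rate <- rates$rate[rates$experiment_id == reference_experiment]
    rates$fold <- signif(vapply(rates$rate, fold_effect, numeric(1),
                                rate_proficient = ref_rate), 3)
  }

  spectrum <- NULL; factors <- NULL; per_bp <- NULL
  if (!is.null(spectrum_tsv)) {
    records <- read_spectrum_tsv(spectrum_tsv)
    spectrum <- tally_spectrum(records)
    locus <- .resolve_locus(config)
    factors <- correction_factors(spectrum, locus)
    per_bp <- data.frame(experiment_id = rates$experiment_id,
                         mu_T = rates$rate,
                         mu_b = per_bp_rate(rates$rate, factors),
                         tau = factors$tau,
                         stringsAsFactors = FALSE)
  }
  structure(list(header = .config_header(config), rates = rates,
                 spectrum = spectrum, factors = factors, per_bp = per_bp,
                 config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(paste(x$header, collapse = "\n"), "\n")
  cat("rates:\n")
  print(x$rates)
  if (!is.null(x$spectrum)) print(x$spectrum)
  if (!is.null(x$factors)) print(x$factors)
  if (!is.null(x$per_bp)) { cat("per-bp rates:\n"); print(x$per_bp) }
  invisible(x)
}

#' Write a pipeline report to TSV files
#'
#' Emits `<prefix>_rates.tsv` and, when a spectrum was analyzed,
#' `<prefix>_perbp.tsv`, each preceded by the '#' config header.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param prefix Output path prefix.
#' @return Paths written, invisibly.
#' @export
write_pipeline_report <- function(report, prefix) {
  stopifnot(inherits(report, "pipeline_report"))
  write_one <- function(df, path) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(report$header, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- write_one(report$rates, paste0(prefix, "_rates.tsv"))
  if (!is.null(report$per_bp))
    paths <- c(paths, write_one(report$per_bp, paste0(prefix, "_perbp.tsv")))
  invisible(paths)
}
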