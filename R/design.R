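#' Simulation design for the three-group study
#'
#' Collects every knob of the synthetic-data generator that emulates the
#' healthy (HC) / adenomatous polyp (AP) / colorectal cancer (CRC) small
#' RNA-seq study design: stage-monotone expression effects on a subset of
#' miRNAs, negative binomial count noise with batch and age covariates, and
#' isomiR read structure (end shifts, non-templated A/T tails, a fixed
#' per-miRNA internal substitution, uniform sequencing error, 3' adapter).
#'
#' @param n_hairpins number of precursors (>= 1).
#' @param n_samples_per_group samples per group; groups are fixed as HC, AP,
#'   CRC with ordinal stages 0, 1, 2.
#' @param frac_monotone fraction in \[0, 1\] of miRNAs given a planted
#'   stage-monotone effect.
#' @param lfc_per_step planted log2 fold change per ordinal stage step.
#' @param nb_dispersion NB dispersion alpha >= 0 (0 = Poisson).
#' @param batch_levels number of technical batches.
#' @param batch_sd sd of mean-zero per-batch log2 effects.
#' @param age_slope per-year log2 expression effect of (centered) age.
#' @param baseline_log2 range of per-miRNA baseline log2 mean counts.
#' @param isomir_profile named probabilities over read categories
#'   `canonical`, `trim5`, `trim3`, `ext3`, `add3`, `subst`; must sum to 1.
#' @param seq_error_rate per-base uniform sequencing-error probability.
#' @param adapter 3' adapter appended to every read before cycle clipping
#'   (default: the standard Illumina small-RNA 3' adapter).
#' @param read_length sequencer cycles (single-end).
#' @param qual_degrade_prob fraction of reads whose trailing bases drop
#'   below Q20.
#' @param seed integer seed for all randomness downstream of the design.
#' @return object of class `simulation_design` (a validated list).
#' @export
simulation_design <- function(n_hairpins = 50L,
                              n_samples_per_group = 20L,
                              frac_monotone = 0.1,
                              lfc_per_step = 1,
                              nb_dispersion = 0.1,
                              batch_levels = 2L,
                              batch_sd = 0.1,
                              age_slope = 0.01,
                              baseline_log2 = c(4, 8),
                              isomir_profile = c(canonical = 0.55, trim5 = 0.08,
                                                 trim3 = 0.12, ext3 = 0.08,
                                                 add3 = 0.12, subst = 0.05),
                              seq_error_rate = 0.001,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              read_length = 50L,
                              qual_degrade_prob = 0.05,
                              seed = 1L) {
  if (n_hairpins < 1L) stop("n_hairpins must be >= 1")
  if (n_samples_per_group < 1L) stop("n_samples_per_group must be >= 1")
  if (frac_monotone < 0 || frac_monotone > 1)
    stop("frac_monotone must lie in [0, 1]")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (batch_levels < 1L) stop("batch_levels must be >= 1")
  if (batch_sd < 0 || seq_error_rate < 0 || seq_error_rate > 1)
    stop("invalid noise parameters")
  need <- c("canonical", "trim5", "trim3", "ext3", "add3", "subst")
  if (!setequal(names(isomir_profile), need))
    stop("isomir_profile must have exactly the categories: ",
         paste(need, collapse = ", "))
  isomir_profile <- isomir_profile[need]
  if (any(isomir_profile < 0) || any(isomir_profile > 1) ||
      abs(sum(isomir_profile) - 1) > 1e-8)
    stop("isomir_profile probabilities must lie in [0, 1] and sum to 1")
  if (!grepl("^[ACGT]+$", adapter)) stop("adapter must be over A/C/G/T")
  structure(list(n_hairpins = as.integer(n_hairpins),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 frac_monotone = frac_monotone,
                 lfc_per_step = lfc_per_step,
                 nb_dispersion = nb_dispersion,
                 batch_levels = as.integer(batch_levels),
                 batch_sd = batch_sd,
                 age_slope = age_slope,
                 baseline_log2 = baseline_log2,
                 isomir_profile = isomir_profile,
                 seq_error_rate = seq_error_rate,
                 adapter = adapter,
                 read_length = as.integer(read_length),
                 qual_degrade_prob = qual_degrade_prob,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(paste0(
    "simulation_design: %d hairpins, %d samples/group (HC, AP, CRC)\n",
    "  planted: %.0f%% monotone miRNAs at %.2f log2/step, NB dispersion %.3g\n",
    "  covariates: %d batches (sd %.2f log2), age slope %.3g log2/yr\n",
    "  reads: 1x%d, error %.2g/base, adapter %s\n"),
    x$n_hairpins, x$n_samples_per_group, 100 * x$frac_monotone,
    x$lfc_per_step, x$nb_dispersion, x$batch_levels, x$batch_sd,
    x$age_slope, x$read_length, x$seq_error_rate, x$adapter))
  invisible(x)
}
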