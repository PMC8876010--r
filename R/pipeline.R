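#' Run the full synthetic transition study end to end
#'
#' Convenience wrapper chaining every stage on one simulated study:
#' reference generation, stage-structured count simulation, isomiR read
#' simulation, preprocessing, read assignment and isomiR classification,
#' substitution filtering, count aggregation, size-factor normalization and
#' VST, NB Wald differential expression for the three pairwise contrasts
#' (batch- and age-adjusted), three-way set logic, the ordinal Spearman
#' screen, and positional modification profiles.
#'
#' @param design a [simulation_design()].
#' @param alpha,lfc DE calling thresholds (defaults 0.01 and 0.5).
#' @return list with `reference`, `sim` (counts/metadata/truth), `truth`
#'   (planted isomiR variants), `preprocess_stats`, `profile_stats`,
#'   `calls`, `counts` (miRNA x sample), `isomir_counts`, `size_factors`,
#'   `vst`, `de` (per-contrast `de_result`s), `de_sets`, `three_way`,
#'   `screen`, `profiles`.
#' @export
run_transition_pipeline <- function(design, alpha = 0.01, lfc = 0.5) {
  stopifnot(inherits(design, "simulation_design"))
  ref <- generate_reference(design$n_hairpins, design$seed)
  sim <- simulate_counts(design, ref)
  rd <- simulate_isomir_reads(sim$counts, ref, design)
  reads <- do.call(rbind, lapply(names(rd$reads), function(s) {
    x <- rd$reads[[s]]
    if (nrow(x) > 0L) x$sample <- s
    x
  }))
  pp <- preprocess_reads(reads, design$adapter)
  prof <- profile_reads(pp$reads, ref)
  fcalls <- apply_substitution_filters(prof$calls)
  agg <- aggregate_counts(fcalls, samples = sim$metadata$sample_id)
  counts <- agg$mirna
  sf <- size_factors(counts)
  v <- vst(counts, sf)
  # dispersions are estimated per contrast on the samples actually modeled:
  # the moment estimator is design-blind, so pooling all three groups would
  # fold planted between-group signal into the dispersion
  contrasts <- list(crc_hc = c("CRC", "HC"), ap_hc = c("AP", "HC"),
                    crc_ap = c("CRC", "AP"))
  de <- lapply(contrasts, function(ct)
    nb_wald_test(counts, sim$metadata, contrast = ct,
                 covariates = c("batch", "age"),
                 size_factors = sf[sim$metadata$group %in% ct]))
  de_sets <- lapply(de, call_de, alpha = alpha, lfc = lfc)
  tw <- three_way_summary(de_sets$crc_hc, de_sets$ap_hc, de_sets$crc_ap)
  screen <- spearman_screen(v, sim$metadata$group)
  profiles <- modification_profiles(fcalls,
                                    samples = sim$metadata$sample_id)
  list(reference = ref, sim = sim, truth = rd$truth,
       preprocess_stats = pp$stats, profile_stats = prof$stats,
       calls = fcalls, counts = counts, isomir_counts = agg$isomir,
       size_factors = sf, vst = v, de = de, de_sets = de_sets,
       three_way = tw, screen = screen, profiles = profiles)
}
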