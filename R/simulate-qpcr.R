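#' Simulate raw RT-qPCR Ct tables with technical duplicates
#'
#' Emulates the validation assay design: per sample and assay,
#' `n_wells` duplicate Ct wells with Gaussian well noise. A per-sample
#' input effect (RNA amount) shifts every assay of the sample equally, so
#' delta-Ct normalization removes it. Normalizer assays are constant in
#' expectation across groups; each target's Ct is offset from the
#' normalizers by `base_delta` plus a planted per-group shift (in Ct units;
#' a shift of -2 in CRC means 4-fold higher expression than the reference
#' group).
#'
#' @param metadata data.frame with `sample_id` and `group`.
#' @param shifts named list: target assay id -> named numeric vector of Ct
#'   shifts per group (groups absent from the vector get shift 0).
#' @param seed integer seed.
#' @param normalizers normalizer assay ids.
#' @param base_ct mean normalizer Ct.
#' @param base_delta baseline target minus normalizer Ct.
#' @param sample_sd sd of the per-sample input effect.
#' @param well_sd sd of per-well technical noise.
#' @param n_wells technical replicates per assay (default 2).
#' @return data.frame with `sample_id`, `assay_id`, `well`, `ct`.
#' @export
simulate_qpcr <- function(metadata, shifts, seed,
                          normalizers = c("hsa-miR-16-5p", "hsa-miR-191-5p"),
                          base_ct = 20, base_delta = 4,
                          sample_sd = 0.5, well_sd = 0.15, n_wells = 2L) {
  stopifnot(all(c("sample_id", "group") %in% names(metadata)))
  if (length(unique(metadata$group)) < 2L)
    stop("metadata must contain at least 2 groups")
  set.seed(seed)
  ns <- nrow(metadata)
  sample_eff <- stats::rnorm(ns, 0, sample_sd)
  assays <- c(normalizers, names(shifts))
  true_ct <- matrix(base_ct + sample_eff, ns, length(assays),
                    dimnames = list(metadata$sample_id, assays))
  for (a in names(shifts)) {
    sh <- shifts[[a]]
    g_shift <- ifelse(metadata$group %in% names(sh),
                      sh[metadata$group], 0)
    true_ct[, a] <- true_ct[, a] + base_delta + g_shift
  }
  out <- expand.grid(well = seq_len(n_wells), assay_id = assays,
                     sample_id = metadata$sample_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$ct <- true_ct[cbind(out$sample_id, out$assay_id)] +
    stats::rnorm(nrow(out), 0, well_sd)
  out[, c("sample_id", "assay_id", "well", "ct")]
}
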