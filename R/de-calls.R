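#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#' `NA` p-values are allowed and excluded from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return adjusted p-values, `NA` where the input was `NA`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed features
#'
#' A feature is up-regulated when `p_adj < alpha` and `log2FC > lfc`, and
#' down-regulated when `p_adj < alpha` and `log2FC < -lfc` (both strict).
#'
#' @param results a `de_result` (or any data.frame with `feature_id`,
#'   `log2FC`, `p_adj`).
#' @param alpha FDR threshold (default 0.01).
#' @param lfc absolute log2 fold-change threshold (default 0.5).
#' @return list with character vectors `up` and `down`.
#' @export
call_de <- function(results, alpha = 0.01, lfc = 0.5) {
  sig <- !is.na(results$p_adj) & !is.na(results$log2FC) &
    results$p_adj < alpha
  list(up = results$feature_id[sig & results$log2FC > lfc],
       down = results$feature_id[sig & results$log2FC < -lfc])
}

#' Three-way differential-expression set logic
#'
#' Given up/down sets from the three pairwise contrasts (CRC vs HC, AP vs
#' HC, CRC vs AP), reports the commonly and uniquely deregulated regions:
#' features elevated (or reduced) in both colon conditions against HC,
#' those unique to either condition, and the features shared between
#' HC-and-CRC or HC-and-AP relative to the third group.
#'
#' @param crc_hc,ap_hc,crc_ap lists with `up`/`down` character vectors
#'   ([call_de()] output) for the contrasts CRC vs HC, AP vs HC and
#'   CRC vs AP.
#' @return object of class `three_way_summary`: a list with `regions`
#'   (named list of feature-id vectors) and `counts` (named integer vector).
#' @export
three_way_summary <- function(crc_hc, ap_hc, crc_ap) {
  for (s in list(crc_hc, ap_hc, crc_ap))
    if (!all(c("up", "down") %in% names(s)))
      stop("each contrast must supply up and down sets")
  regions <- list(
    shared_up = intersect(ap_hc$up, crc_hc$up),
    shared_down = intersect(ap_hc$down, crc_hc$down),
    unique_up_crc = setdiff(crc_hc$up, ap_hc$up),
    unique_down_crc = setdiff(crc_hc$down, ap_hc$down),
    unique_up_ap = setdiff(ap_hc$up, crc_hc$up),
    unique_down_ap = setdiff(ap_hc$down, crc_hc$down),
    # up in HC and CRC relative to AP / up in HC and AP relative to CRC
    shared_up_hc_crc = intersect(ap_hc$down, crc_ap$up),
    shared_up_hc_ap = intersect(crc_hc$down, crc_ap$down))
  structure(list(regions = regions,
                 counts = vapply(regions, length, 0L)),
            class = "three_way_summary")
}

#' @export
print.three_way_summary <- function(x, ...) {
  cat("three_way_summary (feature counts per region):\n")
  print(x$counts)
  invisible(x)
}
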