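#' Delta-Ct normalization of raw qPCR wells
#'
#' Per sample: technical-duplicate wells are averaged per assay first; the
#' target's mean Ct minus the arithmetic mean of the normalizers' mean Cts
#' gives the delta Ct. Lower delta Ct means higher expression, so
#' `expression_proxy = -delta_ct` shows the true direction.
#'
#' @param ct data.frame with `sample_id`, `assay_id`, `well`, `ct`.
#' @param target_id assay to normalize.
#' @param normalizer_ids one or more endogenous normalizer assays (e.g.
#'   `"hsa-miR-16-5p"`, `"hsa-miR-191-5p"`).
#' @return data.frame with `sample_id`, `target_id`, `delta_ct`,
#'   `expression_proxy`; samples missing any assay are skipped with a
#'   warning.
#' @export
delta_ct <- function(ct, target_id, normalizer_ids) {
  stopifnot(all(c("sample_id", "assay_id", "ct") %in% names(ct)),
            length(normalizer_ids) >= 1L)
  mean_ct <- function(sample, assay) {
    w <- ct$ct[ct$sample_id == sample & ct$assay_id == assay]
    if (length(w) == 0L) NA_real_ else mean(w)
  }
  samples <- unique(ct$sample_id)
  tgt <- vapply(samples, mean_ct, 0, assay = target_id)
  nrm <- rowMeans(matrix(
    vapply(normalizer_ids, function(a)
      vapply(samples, mean_ct, 0, assay = a), numeric(length(samples))),
    nrow = length(samples)))
  d <- tgt - nrm
  bad <- is.na(d)
  if (any(bad))
    warning(sum(bad), " sample(s) missing an assay; records skipped")
  data.frame(sample_id = samples[!bad], target_id = target_id,
             delta_ct = d[!bad], expression_proxy = -d[!bad],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mann-Whitney group test on delta-Ct records
#'
#' Two-sided Mann-Whitney U per target (exact enumeration when both groups
#' have at most 8 samples and no ties; continuity- and tie-corrected normal
#' approximation otherwise), BH-adjusted across targets. For the contrast "A vs B" the
#' fold change is `log2FC = mean delta Ct(B) - mean delta Ct(A)` -- delta Ct
#' is inverse to expression, so positive log2FC means higher expression in
#' group A. A target is called deregulated when `p_adj < alpha` and
#' `|log2FC| > lfc`.
#'
#' @param records delta-Ct records ([delta_ct()] output, possibly several
#'   targets row-bound).
#' @param groups named group labels (names = sample ids).
#' @param group_a,group_b contrast groups, "A vs B" (A = case, B = control).
#' @param alpha,lfc calling thresholds (defaults 0.05 and 1).
#' @return data.frame with `target_id`, `n_a`, `n_b`, `U`, `p`, `log2FC`,
#'   `p_adj`, `called`.
#' @export
mwu_group_test <- function(records, groups, group_a, group_b,
                           alpha = 0.05, lfc = 1) {
  if (is.null(names(groups)))
    stop("groups must be a named vector (names = sample ids)")
  targets <- unique(records$target_id)
  out <- vector("list", length(targets))
  for (t in seq_along(targets)) {
    rec <- records[records$target_id == targets[t], , drop = FALSE]
    g <- groups[rec$sample_id]
    da <- rec$delta_ct[!is.na(g) & g == group_a]
    db <- rec$delta_ct[!is.na(g) & g == group_b]
    if (length(da) < 2L || length(db) < 2L)
      stop("each contrast group needs >= 2 samples with records")
    exact <- length(da) <= 8L && length(db) <= 8L &&
      !anyDuplicated(c(da, db))
    w <- suppressWarnings(
      stats::wilcox.test(da, db, exact = exact, correct = TRUE))
    out[[t]] <- data.frame(target_id = targets[t],
                           n_a = length(da), n_b = length(db),
                           U = unname(w$statistic), p = w$p.value,
                           log2FC = mean(db) - mean(da),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_adj <- bh_adjust(res$p)
  res$called <- res$p_adj < alpha & abs(res$log2FC) > lfc
  res
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1),
#' upper-tail chi-squared p. Rows or columns with zero margins are dropped
#' with a warning.
#'
#' @param table matrix of non-negative integer counts, at least 2x2.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
pearson_chi_squared <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L || sum(table) == 0)
    stop("need a table of at least 2x2 with positive total")
  zr <- rowSums(table) == 0
  zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s)")
    table <- table[!zr, !zc, drop = FALSE]
    if (nrow(table) < 2L || ncol(table) < 2L)
      stop("table degenerate after dropping zero margins")
  }
  r <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(r$statistic), df = unname(r$parameter),
       p_value = r$p.value)
}

#' Tie-corrected Kruskal-Wallis test
#'
#' @param values numeric vector.
#' @param groups group labels, same length (>= 2 non-empty groups).
#' @return list with `statistic` (H), `df`, `p_value`; when all values are
#'   identical the test is degenerate and `p_value = 1`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 non-empty groups")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = nlevels(groups) - 1L, p_value = 1))
  k <- stats::kruskal.test(values, groups)
  list(statistic = unname(k$statistic), df = unname(k$parameter),
       p_value = k$p.value)
}

#' Chi-squared report over the cohort fixture tables
#'
#' Runs [pearson_chi_squared()] on each categorical cohort table and emits
#' one row per (variable, cohort).
#'
#' @param fixture a [cohort_fixture()] (the default).
#' @return data.frame with `variable`, `cohort`, `statistic`, `df`, `p`.
#' @export
cohort_report <- function(fixture = cohort_fixture()) {
  spec <- list(
    c("sex", "profiling", "sex_profiling"),
    c("sex", "validation", "sex_validation"),
    c("smoking", "profiling", "smoking_profiling"),
    c("smoking", "validation", "smoking_validation"),
    c("type", "both", "type_ap"),
    c("stage", "both", "stage_by_cohort"))
  out <- lapply(spec, function(s) {
    r <- pearson_chi_squared(fixture[[s[3L]]])
    data.frame(variable = s[1L], cohort = s[2L], statistic = r$statistic,
               df = r$df, p = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
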