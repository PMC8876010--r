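#' Classical MDS of sample miRNomes
#'
#' Torgerson MDS on Euclidean distances between sample columns of a
#' variance-stabilized expression matrix. Axes are ordered by eigenvalue and
#' given a fixed sign convention: the coordinate of largest magnitude on
#' each axis is made positive.
#'
#' @param x numeric matrix, features x samples (e.g. [vst()] output).
#' @param n_dims number of dimensions (default 2).
#' @return list with `points` (samples x n_dims coordinates) and `eig`
#'   (eigenvalues).
#' @export
mds_samples <- function(x, n_dims = 2L) {
  x <- as.matrix(x)
  if (ncol(x) < n_dims + 1L)
    stop("need at least n_dims + 1 samples")
  d <- stats::dist(t(x))
  fit <- stats::cmdscale(d, k = n_dims, eig = TRUE)
  pts <- fit$points
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  list(points = pts, eig = fit$eig)
}

#' Spearman screen for stage-monotone features
#'
#' Per feature, Spearman's rank correlation (average ranks for ties)
#' between expression and the ordinal disease stage (HC = 0, AP = 1,
#' CRC = 2). Features are tiered: `high` when `|rho| > 0.7`, `moderate`
#' when `0.5 < |rho| <= 0.7`, `none` otherwise (the boundary point 0.7 is
#' moderate by the strict reading of the high tier).
#'
#' @param x numeric matrix, features x samples.
#' @param stages integer ordinal stages per sample, or group labels
#'   accepted by [stage_encoding()].
#' @return data.frame with `feature_id`, `rho`, `tier`, `direction`
#'   (constant features get `rho = NA`, tier `none`).
#' @export
spearman_screen <- function(x, stages) {
  x <- as.matrix(x)
  if (is.character(stages) || is.factor(stages))
    stages <- stage_encoding(stages)
  stopifnot(length(stages) == ncol(x))
  if (length(unique(stages)) < 2L)
    stop("need at least 2 distinct stages")
  rho <- suppressWarnings(
    apply(x, 1L, function(v)
      if (stats::sd(v) == 0) NA_real_
      else stats::cor(v, stages, method = "spearman")))
  tier <- rep("none", length(rho))
  tier[!is.na(rho) & abs(rho) > 0.5 & abs(rho) <= 0.7] <- "moderate"
  tier[!is.na(rho) & abs(rho) > 0.7] <- "high"
  direction <- ifelse(is.na(rho) | rho == 0, NA_character_,
                      ifelse(rho > 0, "increasing", "decreasing"))
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("feature%05d", seq_len(nrow(x)))
  data.frame(feature_id = ids, rho = rho, tier = tier,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Kruskal-Wallis tests on positional modification abundances
#'
#' For every (modification type, signed position), a tie-corrected
#' Kruskal-Wallis test of per-sample abundances across groups (chi-squared
#' reference, df = groups - 1), BH-adjusted across all (type, position)
#' tests. Samples absent from a profile cell carry abundance 0. Group
#' medians are reported to expose monotone trends.
#'
#' @param profiles long data.frame from [modification_profiles()].
#' @param groups named group labels: names must be sample ids covering all
#'   profiled samples (and may include samples with no modifications).
#' @return data.frame with `type`, `position`, `H`, `df`, `p`, `p_adj` and
#'   one `median_<group>` column per group.
#' @export
kruskal_positional <- function(profiles, groups) {
  if (is.null(names(groups)))
    stop("groups must be a named vector (names = sample ids)")
  samples <- names(groups)
  if (!all(profiles$sample %in% samples))
    stop("profiles contain samples absent from groups")
  gf <- factor(groups)
  if (nlevels(gf) < 2L || any(table(gf) < 2L))
    stop("need >= 2 groups with >= 2 samples each")
  cells <- unique(profiles[, c("type", "position")])
  out <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    sel <- profiles$type == cells$type[r] &
      profiles$position == cells$position[r]
    ab <- stats::setNames(rep(0, length(samples)), samples)
    ab[profiles$sample[sel]] <- profiles$abundance[sel]
    kw <- kruskal_wallis(ab, gf)
    med <- tapply(ab, gf, stats::median)
    out[[r]] <- data.frame(type = cells$type[r],
                           position = cells$position[r],
                           H = kw$statistic, df = kw$df, p = kw$p_value,
                           t(stats::setNames(as.numeric(med),
                                             paste0("median_", levels(gf)))),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$type, res$position), , drop = FALSE]
  res$p_adj <- bh_adjust(res$p)
  med_cols <- grep("^median_", names(res), value = TRUE)
  rownames(res) <- NULL
  res[, c("type", "position", "H", "df", "p", "p_adj", med_cols)]
}
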