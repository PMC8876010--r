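#' Median-of-ratios size factors
#'
#' Per-sample scale factors correcting sequencing depth: each sample's
#' factor is the median, over features positive in every sample, of the
#' ratio of its count to the feature's geometric mean across samples.
#'
#' @param counts non-negative matrix, features x samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has positive counts in every sample; size factors ",
         "cannot be estimated (consider a pseudo-reference fallback)")
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  s <- apply(exp(log(counts[pos, , drop = FALSE]) - logg), 2L, stats::median)
  names(s) <- colnames(counts)
  s
}

#' Variance-stabilizing transform of normalized counts
#'
#' A monotone log-based transform, `log2(count / s + pseudocount)`, that
#' flattens the count-variance trend enough for Euclidean-distance analyses
#' (MDS) and rank-based screening downstream.
#'
#' @param counts non-negative matrix, features x samples.
#' @param size_factors positive per-sample factors (estimated with
#'   [size_factors()] when omitted).
#' @param pseudocount added after depth scaling (default 1, so a zero count
#'   maps to 0).
#' @return numeric matrix of the same shape.
#' @export
vst <- function(counts, size_factors = NULL, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- size_factors(counts)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2L, size_factors, "/") + pseudocount)
}

#' Per-feature NB dispersion estimates
#'
#' Method-of-moments dispersion on normalized counts,
#' `max(0, (s^2 - mean) / mean^2)`, shrunk 50/50 toward the mean-dispersion
#' trend `alpha(mu) = a1/mu + a0` fitted across features by least squares,
#' floored at 1e-8.
#'
#' @param counts non-negative matrix, features x samples (>= 2 samples).
#' @param size_factors optional per-sample factors.
#' @return named numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("dispersion estimation needs at least 2 samples")
  if (is.null(size_factors)) size_factors <- size_factors(counts)
  norm <- sweep(counts, 2L, size_factors, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  raw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  use <- mu > 0
  trend <- raw
  if (sum(use) >= 3L && stats::var(1 / mu[use]) > 0) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[use]), raw[use])
    trend[use] <- pmax(0, fit$coefficients[1L] +
                         fit$coefficients[2L] / mu[use])
  }
  out <- pmax(1e-8, 0.5 * raw + 0.5 * trend)
  out[v == 0] <- 1e-8          # constant features carry no variance signal
  names(out) <- rownames(counts)
  out
}
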