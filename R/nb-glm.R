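# Negative binomial GLM Wald differential expression --------------------------
#
# Per feature, a log-link NB GLM with fixed dispersion and log size-factor
# offset is fitted by iteratively reweighted least squares (Fisher scoring
# with weights mu / (1 + alpha * mu)); the Wald statistic on the contrast
# coefficient is referred to the standard normal.

nb_irls <- function(y, X, offset, alpha, maxit = 50L, tol = 1e-8) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    w <- mu / (1 + alpha * mu)
    z <- eta - offset + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    beta_new <- fit$coefficients
    eta <- drop(X %*% beta_new) + offset
    eta <- pmin(pmax(eta, -30), 30)          # guard against separation
    mu <- exp(eta)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      w <- mu / (1 + alpha * mu)
      XtWX <- crossprod(X * w, X)
      cov <- tryCatch(solve(XtWX), error = function(e) NULL)
      if (is.null(cov)) return(NULL)
      return(list(beta = beta, se = sqrt(diag(cov)), converged = TRUE))
    }
  }
  NULL
}

#' NB-GLM Wald test for a group contrast with covariates
#'
#' Fits, per feature, `log mu = X beta + log(size factor)` with a fixed
#' per-feature dispersion and tests the contrast group coefficient with a
#' Wald z against the standard normal. The default design adjusts for
#' technical batch and centered age. Features that fail to converge (e.g.
#' separation) are flagged, get `p = NA`, and are excluded from the BH
#' adjustment.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param metadata data.frame with `group` and any covariate columns; rows
#'   in column order of `counts`.
#' @param contrast length-2 character vector `c(test, reference)`, e.g.
#'   `c("CRC", "HC")`.
#' @param covariates character vector of metadata columns to adjust for
#'   (default `c("batch", "age")`; `age` is centered, `batch` coerced to a
#'   factor). Use `character()` for an unadjusted fit.
#' @param size_factors,dispersions optional; estimated from `counts` when
#'   omitted.
#' @param maxit,tol IRLS controls.
#' @return a `de_result` data.frame: `feature_id`, `baseMean`, `log2FC`,
#'   `se` (log2 scale), `wald_z`, `p`, `p_adj`, `converged`, with the
#'   contrast stored as an attribute.
#' @export
nb_wald_test <- function(counts, metadata, contrast = c("CRC", "HC"),
                         covariates = c("batch", "age"),
                         size_factors = NULL, dispersions = NULL,
                         maxit = 50L, tol = 1e-8) {
  counts <- as.matrix(counts)
  stopifnot(nrow(metadata) == ncol(counts), "group" %in% names(metadata),
            length(contrast) == 2L)
  if (!all(contrast %in% metadata$group))
    stop("contrast groups absent from metadata")
  keep <- metadata$group %in% contrast
  counts <- counts[, keep, drop = FALSE]
  metadata <- metadata[keep, , drop = FALSE]
  group <- stats::relevel(factor(metadata$group, levels = contrast[c(2L, 1L)]),
                          ref = contrast[2L])
  terms <- list(group = group)
  for (cv in covariates) {
    if (!cv %in% names(metadata)) stop("covariate not in metadata: ", cv)
    v <- metadata[[cv]]
    if (cv == "age") v <- as.numeric(v) - mean(as.numeric(v))
    if (cv == "batch") v <- factor(v)
    if (is.factor(v) && nlevels(droplevels(v)) < 2L) next
    if (is.numeric(v) && stats::var(v) == 0) next
    terms[[cv]] <- if (is.factor(v)) droplevels(v) else v
  }
  X <- stats::model.matrix(~ ., data = as.data.frame(terms))
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  coef_idx <- match(paste0("group", contrast[1L]), colnames(X))

  if (is.null(size_factors)) size_factors <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts,
                                                               size_factors)
  offset <- log(size_factors)
  nf <- nrow(counts)
  log2fc <- se <- z <- p <- rep(NA_real_, nf)
  conv <- logical(nf)
  base_mean <- rowMeans(sweep(counts, 2L, size_factors, "/"))
  ln2 <- log(2)
  for (i in seq_len(nf)) {
    fit <- nb_irls(counts[i, ], X, offset, dispersions[i],
                   maxit = maxit, tol = tol)
    if (is.null(fit) || !is.finite(fit$se[coef_idx]) ||
        fit$se[coef_idx] <= 0) next
    conv[i] <- TRUE
    log2fc[i] <- fit$beta[coef_idx] / ln2
    se[i] <- fit$se[coef_idx] / ln2
    z[i] <- fit$beta[coef_idx] / fit$se[coef_idx]
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("feature%05d", seq_len(nf))
  res <- data.frame(feature_id = ids, baseMean = base_mean, log2FC = log2fc,
                    se = se, wald_z = z, p = p, p_adj = bh_adjust(p),
                    converged = conv, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("de_result: %s vs %s, %d features (%d converged)\n",
              ct[1L], ct[2L], nrow(x), sum(x$converged)))
  cat(sprintf("  p_adj < 0.01 & |log2FC| > 0.5: %d\n",
              sum(x$p_adj < 0.01 & abs(x$log2FC) > 0.5, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
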