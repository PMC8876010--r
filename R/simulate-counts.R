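#' Simulate stage-structured miRNA counts with covariates
#'
#' Draws a features-by-samples negative binomial count matrix under the
#' generative model
#' \deqn{\log_2 \mu_{is} = b_i + d_i \cdot \ell \cdot \mathrm{stage}_s \cdot
#'   m_i + \beta_{\mathrm{batch}(s)} + a \cdot (\mathrm{age}_s - \overline{\mathrm{age}})}
#' with stage encoded HC = 0, AP = 1, CRC = 2, per-miRNA baseline \eqn{b_i},
#' monotone indicator \eqn{m_i} with direction \eqn{d_i \in \{+1, -1\}},
#' planted per-step effect \eqn{\ell}, mean-zero batch effects and a linear
#' age effect. Counts are NB with dispersion `nb_dispersion` (Poisson when 0).
#'
#' @param design a [simulation_design()].
#' @param reference optional `mir_reference`; its mature ids label the rows
#'   (it must have `design$n_hairpins` hairpins).
#' @return list with `counts` (integer matrix), `metadata` (data.frame:
#'   `sample_id`, `group`, `stage`, `age`, `batch`) and `truth` (data.frame:
#'   `mature_id`, `is_monotone`, `direction`, `true_lfc_per_step`,
#'   `baseline_log2`).
#' @export
simulate_counts <- function(design, reference = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "mir_reference"))
    if (nrow(reference$mature) != design$n_hairpins)
      stop("reference size does not match design$n_hairpins")
    ids <- reference$mature$mature_id
  } else {
    ids <- sprintf("hp%04d-mir", seq_len(design$n_hairpins))
  }
  set.seed(design$seed)
  nf <- design$n_hairpins
  n <- design$n_samples_per_group
  groups <- rep(c("HC", "AP", "CRC"), each = n)
  stage <- stage_encoding(groups)
  ns <- length(groups)
  sample_id <- sprintf("s%03d", seq_len(ns))
  age <- round(stats::runif(ns, 45, 80))
  batch <- sample(seq_len(design$batch_levels), ns, replace = TRUE)
  batch_eff <- stats::rnorm(design$batch_levels, 0, design$batch_sd)
  batch_eff <- batch_eff - mean(batch_eff)

  baseline <- stats::runif(nf, design$baseline_log2[1], design$baseline_log2[2])
  is_mono <- stats::runif(nf) < design$frac_monotone
  direction <- sample(c(-1L, 1L), nf, replace = TRUE)
  lfc <- ifelse(is_mono, design$lfc_per_step, 0)

  log2mu <- outer(baseline, rep(0, ns), `+`) +
    outer(direction * lfc, stage) +
    matrix(rep(batch_eff[batch], each = nf), nf, ns) +
    matrix(rep(design$age_slope * (age - mean(age)), each = nf), nf, ns)
  mu <- 2^log2mu
  counts <- if (design$nb_dispersion == 0) {
    matrix(stats::rpois(nf * ns, lambda = mu), nf, ns)
  } else {
    matrix(stats::rnbinom(nf * ns, mu = mu, size = 1 / design$nb_dispersion),
           nf, ns)
  }
  dimnames(counts) <- list(ids, sample_id)
  list(counts = counts,
       metadata = data.frame(sample_id = sample_id, group = groups,
                             stage = stage, age = age, batch = factor(batch),
                             stringsAsFactors = FALSE),
       truth = data.frame(mature_id = ids, is_monotone = is_mono,
                          direction = direction,
                          true_lfc_per_step = direction * lfc,
                          baseline_log2 = baseline,
                          stringsAsFactors = FALSE))
}
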