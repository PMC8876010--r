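#' miRNA seed sequence (positions 2-8)
#'
#' @param mature mature miRNA sequence, length >= 8, over A/C/G/T.
#' @return the 7-nt seed.
#' @export
seed_of <- function(mature) {
  stopifnot(length(mature) == 1L)
  if (nchar(mature) < 8L) stop("mature sequence must be >= 8 nt")
  substr(mature, 2L, 8L)
}

#' 8-mer seed-site motif of a miRNA
#'
#' The canonical 8-mer site: perfect Watson-Crick complement of miRNA
#' positions 2-8 followed by an adenosine opposite position 1 (the `A` is
#' matched literally in the UTR regardless of the miRNA's first
#' nucleotide).
#'
#' @param mature mature miRNA sequence (>= 8 nt).
#' @return the 8-nt DNA motif to search on the UTR.
#' @export
site_motif <- function(mature) paste0(revcomp(seed_of(mature)), "A")

#' Scan a 3'UTR for 8-mer seed sites
#'
#' Reports every (possibly overlapping) occurrence of the miRNA's 8-mer
#' motif with 1-based inclusive coordinates on the UTR (5' to 3'), ordered
#' by start.
#'
#' @param utr 3'UTR sequence over A/C/G/T.
#' @param mature mature miRNA sequence (>= 8 nt).
#' @param utr_id,mature_id optional identifiers copied to the output.
#' @return data.frame with `utr_id`, `mature_id`, `start`, `end`,
#'   `site_type` (always "8mer"); zero rows when no site exists.
#' @export
find_8mer_sites <- function(utr, mature, utr_id = NA_character_,
                            mature_id = NA_character_) {
  stopifnot(length(utr) == 1L)
  if (!grepl("^[ACGT]*$", utr)) stop("UTR must be over A/C/G/T")
  motif <- site_motif(mature)
  L <- nchar(utr)
  starts <- if (L >= 8L) which(substring(utr, 1:(L - 7L), 8:L) == motif)
            else integer(0)
  data.frame(utr_id = rep(utr_id, length(starts)),
             mature_id = rep(mature_id, length(starts)),
             start = starts, end = starts + 7L,
             site_type = rep("8mer", length(starts)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher overrepresentation analysis of pathway gene sets
#'
#' Per pathway: the upper-tail hypergeometric probability of observing at
#' least `k` target genes in the pathway (Fisher's exact test,
#' one-sided), the enrichment score `E = (k/n)/(K/N)`, BH adjustment across
#' pathways, and the significance call `p_adj < alpha & E > 1` (strict).
#'
#' @param targets character vector of target genes (subset of `universe`).
#' @param pathways named list of gene vectors, or a data.frame with
#'   `pathway_id` and `gene_id`.
#' @param universe character vector of all considered genes.
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @return data.frame with `pathway_id`, `k`, `K`, `n`, `N`, `E`, `p`,
#'   `p_adj`, `significant`.
#' @export
fisher_ora <- function(targets, pathways, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe must be non-empty")
  if (is.data.frame(pathways))
    pathways <- split(pathways$gene_id, pathways$pathway_id)
  targets <- unique(targets)
  if (!all(targets %in% universe))
    stop("targets must be a subset of the universe")
  if (!all(unlist(pathways) %in% universe))
    stop("every pathway must be a subset of the universe")
  N <- length(universe)
  n <- length(targets)
  K <- vapply(pathways, function(g) length(unique(g)), 0L)
  k <- vapply(pathways, function(g)
    length(intersect(unique(g), targets)), 0L)
  E <- ifelse(K > 0L & n > 0L, (k / n) / (K / N), 0)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(pathway_id = names(pathways), k = k, K = K, n = n,
                    N = N, E = E, p = p, p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$significant <- res$p_adj < alpha & res$E > 1
  res
}
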