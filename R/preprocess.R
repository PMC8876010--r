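# Adapter + quality trimming and length filtering of small-RNA reads.
# All three operations are vectorized over reads; the pipeline wrapper
# additionally collapses duplicate (sequence, quality) pairs, which makes
# preprocessing cost scale with library complexity rather than depth.

# cut positions (number of 5' bases kept) for a 3' adapter, per read.
# Semi-global, mismatches only (no indels): candidate occurrences are every
# start offset p; the match length is min(adapter length, bases left), i.e.
# a full internal match or a 3'-terminal prefix match. A candidate is valid
# when overlap >= min_overlap and mismatches <= floor(rate * overlap); the
# best candidate maximizes matching bases (overlap - mismatches), ties going
# to the leftmost occurrence.
adapter_cut_positions <- function(sequences, adapter, max_error_rate,
                                  min_overlap) {
  a_ch <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  alen <- length(a_ch)
  keep <- nchar(sequences)                       # default: no cut
  for (L in unique(nchar(sequences))) {
    if (L < min_overlap) next
    idx <- which(nchar(sequences) == L)
    M <- matrix(unlist(strsplit(sequences[idx], "", fixed = TRUE),
                       use.names = FALSE), nrow = length(idx), byrow = TRUE)
    best_score <- rep(-1L, length(idx))
    best_cut <- rep(L, length(idx))
    for (p in seq_len(L - min_overlap + 1L)) {
      m <- min(alen, L - p + 1L)
      mm <- rowSums(M[, p:(p + m - 1L), drop = FALSE] !=
                      matrix(a_ch[seq_len(m)], length(idx), m, byrow = TRUE))
      score <- m - mm
      valid <- mm <= floor(max_error_rate * m) & score > best_score
      best_score[valid] <- score[valid]
      best_cut[valid] <- p - 1L
    }
    keep[idx] <- best_cut
  }
  keep
}

#' Trim a 3' adapter from reads
#'
#' Removes the best-scoring occurrence of the adapter -- a full internal
#' match or a 3'-terminal prefix match, allowing mismatches up to
#' `floor(max_error_rate * overlap)` -- and everything 3' of it. Reads with
#' no valid occurrence are returned unchanged. Qualities, when supplied, are
#' trimmed in lockstep.
#'
#' @param sequence character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param quality optional Phred+33 quality strings (same lengths).
#' @param max_error_rate allowed mismatch fraction of the matched length,
#'   in \[0, 0.5).
#' @param min_overlap minimum matched length for a 3'-terminal partial
#'   occurrence to count (guards against chance 1-2 nt matches).
#' @return list with `sequence`, `quality` (NULL if not supplied) and
#'   `trimmed` (logical: an occurrence was removed).
#' @examples
#' trim_adapter("ACGTACGTACGTAAGATCGGAAGAGC", "AGATCGGAAGAGC")$sequence
#' @export
trim_adapter <- function(sequence, adapter, quality = NULL,
                         max_error_rate = 0.1, min_overlap = 3L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (max_error_rate < 0 || max_error_rate >= 0.5)
    stop("max_error_rate must lie in [0, 0.5)")
  if (!is.null(quality) && any(nchar(quality) != nchar(sequence)))
    stop("sequence/quality length mismatch")
  keep <- adapter_cut_positions(sequence, adapter, max_error_rate,
                                as.integer(min_overlap))
  list(sequence = substr(sequence, 1L, keep),
       quality = if (!is.null(quality)) substr(quality, 1L, keep),
       trimmed = keep < nchar(sequence))
}

# number of 5' bases kept by the partial-sum 3' quality trimming rule for
# one quality string: over cut points j, the running sum from the 3' end of
# (threshold - q_i) is maximized; bases j..L are removed when that maximum
# is positive (ties resolve to the shortest trim).
quality_keep_one <- function(quality, threshold) {
  L <- nchar(quality)
  if (L == 0L) return(0L)
  d <- threshold - (utf8ToInt(quality) - 33L)
  s <- rev(cumsum(rev(d)))                # s[j] = sum_{i=j..L} d_i
  j <- max(which(s == max(s)))
  if (s[j] > 0) j - 1L else L
}

#' Quality-trim the 3' end of reads
#'
#' Standard partial-sum rule (as used by cutadapt/BWA): trailing bases are
#' removed at the cut point maximizing the running 3' sum of
#' `(threshold - q)`; with monotone qualities all retained terminal bases
#' are at or above the threshold.
#'
#' @param sequence character vector of read sequences.
#' @param quality Phred+33 quality strings (same lengths).
#' @param threshold Phred quality cutoff (default Q20).
#' @return list with trimmed `sequence` and `quality`.
#' @export
quality_trim <- function(sequence, quality, threshold = 20L) {
  if (any(nchar(quality) != nchar(sequence)))
    stop("sequence/quality length mismatch")
  uq <- unique(quality)
  keep_u <- vapply(uq, quality_keep_one, 0L, threshold = threshold)
  keep <- keep_u[match(quality, uq)]
  list(sequence = substr(sequence, 1L, keep),
       quality = substr(quality, 1L, keep))
}

#' Filter reads by minimum length
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param min_len minimum kept length in nt (default 18, the conventional
#'   lower bound of genuine miRNA inserts).
#' @return list with `reads` (kept rows) and `stats`
#'   (`n_input`, `n_kept`, `n_discarded_short`).
#' @export
filter_length <- function(reads, min_len = 18L) {
  keep <- nchar(reads$sequence) >= min_len
  list(reads = reads[keep, , drop = FALSE],
       stats = list(n_input = nrow(reads), n_kept = sum(keep),
                    n_discarded_short = sum(!keep)))
}

#' Preprocess raw small-RNA reads
#'
#' Adapter trimming, then 3' quality trimming, then length filtering.
#' Duplicate (sequence, quality) pairs are collapsed internally so the cost
#' scales with the number of distinct reads. The default `min_overlap` of
#' half the adapter length suits 1x50 small-RNA chemistry, where the full
#' adapter is sequenced in virtually every read; it makes preprocessing
#' idempotent up to a ~4^-10 per-read chance of a spurious re-trim.
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param adapter 3' adapter sequence.
#' @param max_error_rate adapter mismatch budget (fraction of overlap).
#' @param min_overlap minimum adapter overlap (see Details).
#' @param q_threshold Phred cutoff for 3' quality trimming.
#' @param min_len minimum read length kept.
#' @return list with `reads` (preprocessed, inputs shorter than `min_len`
#'   dropped) and `stats` (`n_input`, `n_adapter_trimmed`,
#'   `n_discarded_short`, `n_kept`).
#' @export
preprocess_reads <- function(reads, adapter,
                             max_error_rate = 0.1,
                             min_overlap = nchar(adapter) %/% 2L,
                             q_threshold = 20L, min_len = 18L) {
  key <- paste(reads$sequence, reads$quality, sep = "\r")
  uidx <- which(!duplicated(key))
  map <- match(key, key[uidx])
  at <- trim_adapter(reads$sequence[uidx], adapter,
                     quality = reads$quality[uidx],
                     max_error_rate = max_error_rate,
                     min_overlap = min_overlap)
  qt <- quality_trim(at$sequence, at$quality, threshold = q_threshold)
  out <- reads                       # extra columns (e.g. sample) pass through
  out$sequence <- qt$sequence[map]
  out$quality <- qt$quality[map]
  fl <- filter_length(out, min_len = min_len)
  list(reads = fl$reads,
       stats = list(n_input = nrow(reads),
                    n_adapter_trimmed = sum(at$trimmed[map]),
                    n_discarded_short = fl$stats$n_discarded_short,
                    n_kept = fl$stats$n_kept))
}
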