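#' Apply the substitution credibility filters to isomiR calls
#'
#' Two rules reduce false-positive substitutions: (1) substitution-bearing
#' calls whose reads did not map uniquely are discarded; (2) within each
#' sample and miRNA, a substitution `(position, ref, alt)` is kept only when
#' the fraction of the miRNA's reads carrying it is at least `min_fraction`
#' (default 0.25); below that it is deemed sequencing error and its reads are
#' merged into the call with identical end offsets and tail and no
#' substitution. Total read counts per miRNA are conserved except through
#' the unique-mapping discard.
#'
#' @param calls a `calls` data.frame from [profile_reads()].
#' @param min_fraction minimum substitution fraction (default 0.25; the
#'   threshold is inclusive).
#' @return filtered and re-aggregated calls data.frame.
#' @export
apply_substitution_filters <- function(calls, min_fraction = 0.25) {
  calls <- calls[!(calls$subs != "" & !calls$unique), , drop = FALSE]
  if (nrow(calls) == 0L) return(calls)
  g <- paste(calls$sample, calls$mature_id, sep = "\r")
  total <- tapply(calls$count, g, sum)[g]
  has <- which(calls$subs != "")
  if (length(has) > 0L) {
    toks <- strsplit(calls$subs[has], ";", fixed = TRUE)
    row_l <- rep(has, lengths(toks))
    tok_l <- unlist(toks, use.names = FALSE)
    tkey <- paste(g[row_l], tok_l, sep = "\r")
    tok_count <- tapply(calls$count[row_l], tkey, sum)
    frac <- tok_count[tkey] / total[row_l]
    keep <- frac >= min_fraction
    calls$subs[has] <- ""
    if (any(keep)) {
      kept <- tapply(tok_l[keep], row_l[keep],
                     function(t) paste(t[order(as.integer(
                       sub(":.*$", "", t)))], collapse = ";"))
      calls$subs[as.integer(names(kept))] <- unname(kept)
    }
  }
  ckey <- paste(calls$sample, calls$mature_id, calls$offset5, calls$offset3,
                calls$tail, calls$subs, sep = "\r")
  cnt <- tapply(calls$count, ckey, sum)
  uni <- tapply(calls$unique, ckey, all)
  first <- !duplicated(ckey)
  out <- calls[first, , drop = FALSE]
  out$count <- as.integer(cnt[ckey[first]])
  out$unique <- as.logical(uni[ckey[first]])
  out <- out[order(out$sample, out$mature_id, out$offset5, out$offset3,
                   out$tail, out$subs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate isomiR calls into count matrices
#'
#' @param calls a calls data.frame ([profile_reads()] /
#'   [apply_substitution_filters()]).
#' @param samples optional character vector fixing the column set (samples
#'   without assigned reads get all-zero columns).
#' @return list with `mirna` (miRNA-level integer matrix), `isomir`
#'   (isomiR-level matrix keyed `mature|offset5|offset3|tail|subs`) and
#'   `isomir_key` (data.frame decoding the isomiR row keys).
#' @export
aggregate_counts <- function(calls, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  key <- sprintf("%s|%d|%d|%s|%s", calls$mature_id, calls$offset5,
                 calls$offset3, calls$tail, calls$subs)
  ukey <- sort(unique(key))
  iso <- matrix(0L, length(ukey), length(samples),
                dimnames = list(ukey, samples))
  if (anyDuplicated(paste(key, calls$sample))) {   # guard; upstream aggregates
    for (r in seq_len(nrow(calls))) {
      i <- match(key[r], ukey); j <- match(calls$sample[r], samples)
      iso[i, j] <- iso[i, j] + calls$count[r]
    }
  } else {
    iso[cbind(match(key, ukey), match(calls$sample, samples))] <- calls$count
  }
  first <- !duplicated(key)
  ord <- match(ukey, key[first])
  isomir_key <- data.frame(key = ukey,
                           mature_id = calls$mature_id[first][ord],
                           offset5 = calls$offset5[first][ord],
                           offset3 = calls$offset3[first][ord],
                           tail = calls$tail[first][ord],
                           subs = calls$subs[first][ord],
                           stringsAsFactors = FALSE)
  mirna <- rowsum(iso, isomir_key$mature_id)
  storage.mode(mirna) <- "integer"
  list(mirna = mirna, isomir = iso, isomir_key = isomir_key)
}

#' Positional isomiR modification profiles
#'
#' Per sample, modification type and signed position: the fraction of all
#' miRNA-assigned reads in the sample carrying that modification. Types and
#' their position conventions: `5p_shift` at `offset5` (positive = seed
#' shift by 5' trimming, negative = 5' extension); `3p_trim` at negative
#' `offset3`; `3p_templated_ext` at positive `offset3`; `3p_addition` at the
#' non-templated tail length (each tailed read counted once); `substitution`
#' at each signed mature-relative substitution position.
#'
#' @param calls a calls data.frame.
#' @param samples optional character vector fixing the sample set.
#' @return data.frame with `sample`, `type`, `position`, `abundance`.
#' @export
modification_profiles <- function(calls, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  total <- tapply(calls$count, calls$sample, sum)
  rows <- list()
  add <- function(idx, type, pos)
    if (length(idx) > 0L)
      data.frame(sample = calls$sample[idx], type = type, position = pos,
                 count = calls$count[idx], stringsAsFactors = FALSE)
  rows$shift5 <- add(which(calls$offset5 != 0L), "5p_shift",
                     calls$offset5[calls$offset5 != 0L])
  rows$trim3 <- add(which(calls$offset3 < 0L), "3p_trim",
                    calls$offset3[calls$offset3 < 0L])
  rows$ext3 <- add(which(calls$offset3 > 0L), "3p_templated_ext",
                   calls$offset3[calls$offset3 > 0L])
  rows$add3 <- add(which(calls$tail != ""), "3p_addition",
                   nchar(calls$tail[calls$tail != ""]))
  has <- which(calls$subs != "")
  if (length(has) > 0L) {
    toks <- strsplit(calls$subs[has], ";", fixed = TRUE)
    idx <- rep(has, lengths(toks))
    pos <- as.integer(sub(":.*$", "",
                          unlist(toks, use.names = FALSE)))
    rows$subs <- data.frame(sample = calls$sample[idx], type = "substitution",
                            position = pos, count = calls$count[idx],
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows[!vapply(rows, is.null, NA)])
  if (is.null(long) || nrow(long) == 0L)
    return(data.frame(sample = character(), type = character(),
                      position = integer(), abundance = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(long$sample, long$type, long$position, sep = "\r")
  cnt <- tapply(long$count, key, sum)
  first <- !duplicated(key)
  out <- data.frame(sample = long$sample[first], type = long$type[first],
                    position = long$position[first],
                    abundance = as.numeric(cnt[key[first]]) /
                      as.numeric(total[long$sample[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample, out$type, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
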