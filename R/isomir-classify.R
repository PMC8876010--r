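# IsomiR classification -------------------------------------------------------
#
# A placed read is described relative to the mature annotation it overlaps:
# signed end offsets (offset5 = read start - mature start, positive = 5'
# trimming / seed shift; offset3 = templated read end - mature end, positive
# = templated 3' extension), a non-templated 3' tail (the greedy run of
# terminal mismatches against the hairpin continuation, at most 3 nt), and
# internal substitutions at signed mature-relative positions (1 = first
# mature base; -1 = one base 5' of it, there is no position 0).

mature_rel_pos <- function(hairpin_pos, mature_start) {
  raw <- hairpin_pos - mature_start + 1L
  ifelse(raw >= 1L, raw, raw - 1L)
}

# core classifier on pre-split read chars; ann = mature rows of one hairpin.
# Returns NULL when no mature annotation overlaps >= min_overlap_frac.
classify_core <- function(rc, hp_idx, start, tail_len, index, mature_by_hp,
                          min_overlap_frac = 0.5) {
  ann <- mature_by_hp[[index$hairpin_ids[hp_idx]]]
  if (is.null(ann)) return(NULL)
  L <- length(rc)
  aligned_len <- L - tail_len
  rend <- start + aligned_len - 1L
  ov <- pmin(rend, ann$end) - pmax(start, ann$start) + 1L
  ok <- which(ov >= min_overlap_frac * (ann$end - ann$start + 1L))
  if (length(ok) == 0L) return(NULL)
  m <- ok[which.max(ov[ok])]
  seg <- index$hairpin_chars[[hp_idx]][start:rend]
  mism <- which(rc[seq_len(aligned_len)] != seg)
  subs <- ""
  if (length(mism) > 0L) {
    pos <- mature_rel_pos(start + mism - 1L, ann$start[m])
    subs <- paste(sprintf("%d:%s>%s", pos, seg[mism], rc[mism]),
                  collapse = ";")
  }
  list(mature_id = ann$mature_id[m],
       offset5 = start - ann$start[m],
       offset3 = rend - ann$end[m],
       tail = if (tail_len > 0L)
         paste(rc[(aligned_len + 1L):L], collapse = "") else "",
       subs = subs)
}

#' Classify one placed read as an isomiR call
#'
#' @param sequence the read sequence.
#' @param placement one row of an [align_read()] result.
#' @param reference a `mir_reference`.
#' @param index optional prebuilt [build_index()] over the same hairpins.
#' @param min_overlap_frac required overlap between the placed read and the
#'   mature annotation, as a fraction of the mature length (default 0.5).
#' @return list with `mature_id`, `offset5`, `offset3`, `tail`, `subs`
#'   (semicolon-joined `pos:REF>ALT` tokens), or NULL when the placement
#'   overlaps no mature annotation (read unassigned).
#' @export
classify_isomir <- function(sequence, placement, reference, index = NULL,
                            min_overlap_frac = 0.5) {
  stopifnot(inherits(reference, "mir_reference"), nrow(placement) == 1L)
  if (is.null(index)) index <- build_index(reference)
  hp_idx <- match(placement$hairpin_id, index$hairpin_ids)
  classify_core(strsplit(sequence, "", fixed = TRUE)[[1L]], hp_idx,
                placement$start, placement$tail_len, index,
                split(reference$mature, reference$mature$hairpin_id),
                min_overlap_frac)
}

#' Assign and classify a read set into per-sample isomiR calls
#'
#' Aligns every distinct read sequence with the k-mer index, classifies the
#' best placements against the mature annotations, and aggregates identical
#' calls. Multi-mapper policy: a read is kept only when all of its
#' minimal-substitution placements classify to the same mature miRNA;
#' otherwise it is counted as unassigned.
#'
#' @param reads a data.frame with `sequence` and `sample` columns, or a
#'   named list of per-sample data.frames with a `sequence` column.
#' @param reference a `mir_reference`.
#' @param k k-mer size for the index.
#' @param max_subs,max_tail see [align_read()].
#' @param min_overlap_frac see [classify_isomir()].
#' @return list with `calls` (data.frame: `sample`, `mature_id`, `offset5`,
#'   `offset3`, `tail`, `subs`, `unique`, `count`) and `stats` (per-sample
#'   `n_reads`, `n_assigned`, `n_unassigned`).
#' @export
profile_reads <- function(reads, reference, k = 12L, max_subs = 2L,
                          max_tail = 3L, min_overlap_frac = 0.5) {
  stopifnot(inherits(reference, "mir_reference"))
  if (is.data.frame(reads)) {
    stopifnot(all(c("sequence", "sample") %in% names(reads)))
    sample_v <- reads$sample
    seq_v <- reads$sequence
  } else {
    stopifnot(is.list(reads), !is.null(names(reads)))
    sample_v <- rep(names(reads), vapply(reads, nrow, 0L))
    seq_v <- unlist(lapply(reads, `[[`, "sequence"), use.names = FALSE)
  }
  index <- build_index(reference$hairpins, k = k)
  mature_by_hp <- split(reference$mature, reference$mature$hairpin_id)

  useq <- unique(seq_v)
  n_u <- length(useq)
  u_mature <- character(n_u); u_o5 <- integer(n_u); u_o3 <- integer(n_u)
  u_tail <- character(n_u); u_subs <- character(n_u); u_uni <- logical(n_u)
  assigned <- logical(n_u)
  for (u in seq_len(n_u)) {
    rc <- strsplit(useq[u], "", fixed = TRUE)[[1L]]
    al <- align_core(rc, index, max_subs = max_subs, max_tail = max_tail)
    if (is.null(al)) next
    best <- which(al$n_subs == min(al$n_subs))
    cls <- lapply(best, function(b)
      classify_core(rc, al$hp[b], al$start[b], al$tail_len[b], index,
                    mature_by_hp, min_overlap_frac))
    if (any(vapply(cls, is.null, NA))) next
    mids <- vapply(cls, `[[`, "", "mature_id")
    if (length(unique(mids)) != 1L) next
    assigned[u] <- TRUE
    u_mature[u] <- mids[1L]
    u_o5[u] <- cls[[1L]]$offset5
    u_o3[u] <- cls[[1L]]$offset3
    u_tail[u] <- cls[[1L]]$tail
    u_subs[u] <- cls[[1L]]$subs
    u_uni[u] <- length(best) == 1L
  }

  map <- match(seq_v, useq)
  samples <- unique(sample_v)
  keep <- assigned[map]
  key <- paste(sample_v[keep], map[keep], sep = "\r")
  agg <- tapply(rep(1L, sum(keep)), key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  s_out <- vapply(parts, `[`, "", 1L)
  u_out <- as.integer(vapply(parts, `[`, "", 2L))
  calls <- data.frame(sample = s_out,
                      mature_id = u_mature[u_out],
                      offset5 = u_o5[u_out], offset3 = u_o3[u_out],
                      tail = u_tail[u_out], subs = u_subs[u_out],
                      unique = u_uni[u_out],
                      count = as.integer(agg),
                      stringsAsFactors = FALSE, row.names = NULL)
  # collapse distinct sequences yielding the same call (e.g. different tails
  # are distinct, but a trimmed read and an error-corrected merge are not)
  ckey <- paste(calls$sample, calls$mature_id, calls$offset5, calls$offset3,
                calls$tail, calls$subs, sep = "\r")
  if (anyDuplicated(ckey)) {
    cnt <- tapply(calls$count, ckey, sum)
    uni <- tapply(calls$unique, ckey, all)
    first <- !duplicated(ckey)
    calls <- calls[first, , drop = FALSE]
    calls$count <- as.integer(cnt[ckey[first]])
    calls$unique <- as.logical(uni[ckey[first]])
  }
  calls <- calls[order(calls$sample, calls$mature_id, calls$offset5,
                       calls$offset3, calls$tail, calls$subs), , drop = FALSE]
  rownames(calls) <- NULL

  n_reads <- table(factor(sample_v, levels = samples))
  n_asg <- table(factor(sample_v[keep], levels = samples))
  stats <- data.frame(sample = samples,
                      n_reads = as.integer(n_reads),
                      n_assigned = as.integer(n_asg),
                      n_unassigned = as.integer(n_reads) - as.integer(n_asg),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(calls = calls, stats = stats)
}
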