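#' Generate a synthetic hairpin reference with mature annotations
#'
#' Draws random miRNA precursor ("hairpin") sequences, each carrying one
#' annotated mature miRNA, for use as an alignment target. Hairpins are
#' 60-90 nt over A/C/G/T, matures are 20-24 nt placed fully inside the
#' hairpin with at least 5 nt flanking either side. Mature sequences are
#' rejection-sampled until they are pairwise distinct and no mature occurs
#' as a substring of any other hairpin, so canonical reads map uniquely.
#'
#' @param n_hairpins number of precursors to generate (>= 1).
#' @param seed integer seed; identical seeds give byte-identical references.
#' @param hairpin_len integer length-2 vector, hairpin length range.
#' @param mature_len integer length-2 vector, mature length range.
#' @param max_retries rejection-sampling budget per hairpin.
#' @return object of class `mir_reference`: a list with `hairpins` (named
#'   character vector) and `mature` (data.frame with `hairpin_id`,
#'   `mature_id`, `start`, `end` -- 1-based inclusive -- and `sequence`).
#' @examples
#' ref <- generate_reference(5, seed = 7)
#' substr(ref$hairpins[1], ref$mature$start[1], ref$mature$end[1]) ==
#'   ref$mature$sequence[1]
#' @export
generate_reference <- function(n_hairpins, seed,
                               hairpin_len = c(60L, 90L),
                               mature_len = c(20L, 24L),
                               max_retries = 1000L) {
  stopifnot(n_hairpins >= 1L, length(hairpin_len) == 2L, length(mature_len) == 2L)
  set.seed(seed)
  hairpins <- character(n_hairpins)
  mat <- vector("list", n_hairpins)
  matures <- character(n_hairpins)
  for (i in seq_len(n_hairpins)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      hlen <- sample(hairpin_len[1]:hairpin_len[2], 1L)
      mlen <- sample(mature_len[1]:mature_len[2], 1L)
      start <- sample(6:(hlen - mlen - 4L), 1L)
      hp <- random_dna(1L, hlen)
      mature <- substr(hp, start, start + mlen - 1L)
      prev <- seq_len(i - 1L)
      clash <-
        mature %in% matures[prev] ||
        any(vapply(prev, function(j)
          grepl(mature, hairpins[j], fixed = TRUE), NA)) ||
        any(vapply(prev, function(j)
          grepl(matures[j], hp, fixed = TRUE), NA))
      if (!clash) {
        hairpins[i] <- hp
        matures[i] <- mature
        mat[[i]] <- data.frame(
          hairpin_id = sprintf("hp%04d", i),
          mature_id = sprintf("hp%04d-mir", i),
          start = start, end = start + mlen - 1L,
          sequence = mature, stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("generate_reference: could not satisfy uniqueness constraints after ",
           max_retries, " retries (reproducibility error)")
  }
  names(hairpins) <- sprintf("hp%04d", seq_len(n_hairpins))
  structure(list(hairpins = hairpins,
                 mature = do.call(rbind, mat)),
            class = "mir_reference")
}

#' @export
print.mir_reference <- function(x, ...) {
  cat(sprintf("mir_reference: %d hairpins (%d-%d nt), %d mature annotations\n",
              length(x$hairpins), min(nchar(x$hairpins)),
              max(nchar(x$hairpins)), nrow(x$mature)))
  invisible(x)
}

#' Write a reference to FASTA + mature annotation TSV
#'
#' The TSV uses 0-based half-open coordinates (`start`, `end`), the
#' convention of BED-like interval files.
#'
#' @param ref a `mir_reference`.
#' @param fasta,mature_tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta, mature_tsv) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$hairpins), fasta)
  out <- data.frame(hairpin_id = ref$mature$hairpin_id,
                    mature_id = ref$mature$mature_id,
                    start = ref$mature$start - 1L,
                    end = ref$mature$end,
                    stringsAsFactors = FALSE)
  utils::write.table(out, mature_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta, mature_tsv))
}

#' Read a reference from FASTA + mature annotation TSV
#'
#' @param fasta hairpin FASTA path.
#' @param mature_tsv annotation TSV path (hairpin_id, mature_id, start, end;
#'   0-based half-open).
#' @return a `mir_reference`.
#' @export
read_reference <- function(fasta, mature_tsv) {
  hp <- Biostrings::readDNAStringSet(fasta)
  hairpins <- as.character(hp)
  names(hairpins) <- sub("\\s.*$", "", names(hp))
  ann <- utils::read.delim(mature_tsv, stringsAsFactors = FALSE)
  bad <- setdiff(ann$hairpin_id, names(hairpins))
  if (length(bad) > 0L)
    stop("mature annotations reference unknown hairpin(s): ",
         paste(bad, collapse = ", "))
  ann$start <- ann$start + 1L           # to 1-based inclusive
  ann$sequence <- substr(hairpins[ann$hairpin_id], ann$start, ann$end)
  structure(list(hairpins = hairpins, mature = ann), class = "mir_reference")
}
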