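# Seed-and-extend assignment of reads to miRNA precursors --------------------
#
# A k-mer index over the hairpin set provides candidate placements; each
# candidate is verified by ungapped comparison. A read's 3'-terminal run of
# consecutive mismatches (plus any overhang past the hairpin end), up to
# `max_tail` nt, is treated as a putative non-templated tail and excluded
# from the substitution count. Detection requires at least one exact k-mer
# shared with the true placement -- the usual sensitivity trade-off of
# seed-and-extend at the default k = 12.

#' Build a k-mer index over a hairpin set
#'
#' Every length-`k` window of every hairpin is retrievable with its
#' (hairpin, offset).
#'
#' @param hairpins named character vector of hairpin sequences, or a
#'   `mir_reference`.
#' @param k window size (default 12).
#' @return object of class `kmer_index`.
#' @export
build_index <- function(hairpins, k = 12L) {
  if (inherits(hairpins, "mir_reference")) hairpins <- hairpins$hairpins
  if (is.null(names(hairpins)) || anyDuplicated(names(hairpins)))
    stop("hairpins must carry unique names")
  k <- as.integer(k)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(hairpins)) {
    h <- hairpins[[i]]
    L <- nchar(h)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(h, starts, starts + k - 1L)
    for (w in seq_along(kmers)) {
      key <- kmers[w]
      env[[key]] <- rbind(env[[key]], c(i, starts[w]))
    }
  }
  structure(list(env = env, k = k,
                 hairpin_ids = names(hairpins),
                 hairpin_chars = strsplit(hairpins, "", fixed = TRUE),
                 hairpin_len = nchar(hairpins)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d hairpins, k = %d, %d distinct k-mers\n",
              length(x$hairpin_ids), x$k, length(ls(x$env))))
  invisible(x)
}

# fast path: read as a character vector; returns NULL or a list of parallel
# vectors (hp index, 1-based start, substitution count, tail length)
align_core <- function(rc, index, max_subs = 2L, max_tail = 3L) {
  L <- length(rc)
  k <- index$k
  if (L < k) return(NULL)
  env <- index$env
  starts <- seq_len(L - k + 1L)
  kmers <- substring(paste(rc, collapse = ""), starts, starts + k - 1L)
  cand <- NULL
  for (w in seq_along(kmers)) {
    hit <- env[[kmers[w]]]
    if (!is.null(hit))
      cand <- rbind(cand, cbind(hit[, 1L], hit[, 2L] - starts[w] + 1L))
  }
  if (is.null(cand)) return(NULL)
  cand <- cand[cand[, 2L] >= 1L, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- unique(cand)
  hp_out <- integer(0); st_out <- integer(0)
  ns_out <- integer(0); tl_out <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; start <- cand[r, 2L]
    hlen <- index$hairpin_len[i]
    avail <- min(L, hlen - start + 1L)
    overhang <- L - avail
    if (overhang > max_tail) next
    seg <- index$hairpin_chars[[i]][start:(start + avail - 1L)]
    mism <- which(rc[seq_len(avail)] != seg)
    run <- 0L
    while (run < (max_tail - overhang) && (avail - run) %in% mism)
      run <- run + 1L
    n_subs <- sum(mism <= avail - run)
    if (n_subs > max_subs) next
    hp_out <- c(hp_out, i); st_out <- c(st_out, start)
    ns_out <- c(ns_out, n_subs); tl_out <- c(tl_out, overhang + run)
  }
  if (length(hp_out) == 0L) return(NULL)
  list(hp = hp_out, start = st_out, n_subs = ns_out, tail_len = tl_out)
}

#' Align one read against the hairpin index
#'
#' Returns all ungapped placements where the read, excluding a putative
#' non-templated 3' tail of at most `max_tail` nt, matches a hairpin with at
#' most `max_subs` substitutions. `unique` is TRUE iff exactly one placement
#' attains the minimal substitution count.
#'
#' @param sequence a single read sequence.
#' @param index a [build_index()] result.
#' @param max_subs maximum substitutions (default 2).
#' @param max_tail maximum non-templated 3' tail length (default 3).
#' @return data.frame with `hairpin_id`, `start` (1-based), `n_subs`,
#'   `tail_len`, `unique`; zero rows when the read is unassigned.
#' @export
align_read <- function(sequence, index, max_subs = 2L, max_tail = 3L) {
  stopifnot(length(sequence) == 1L, inherits(index, "kmer_index"))
  al <- align_core(strsplit(sequence, "", fixed = TRUE)[[1L]], index,
                   max_subs = max_subs, max_tail = max_tail)
  if (is.null(al))
    return(data.frame(hairpin_id = character(), start = integer(),
                      n_subs = integer(), tail_len = integer(),
                      unique = logical(), stringsAsFactors = FALSE))
  best <- min(al$n_subs)
  data.frame(hairpin_id = index$hairpin_ids[al$hp], start = al$start,
             n_subs = al$n_subs, tail_len = al$tail_len,
             unique = sum(al$n_subs == best) == 1L & al$n_subs == best,
             stringsAsFactors = FALSE)
}
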