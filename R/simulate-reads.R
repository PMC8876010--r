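# Planted isomiR variant table ------------------------------------------------

# One row per plantable read variant of each mature miRNA. Tail variants
# enumerate every 1-3 nt non-templated {A,T} tail in which EVERY tail base
# differs from the templated hairpin continuation (this makes the greedy
# 3'-tail caller an exact inverse of the generator). The substitution variant
# sits at a fixed per-miRNA mature position in 4..8: interior, clear of the
# 3' tail caller, and leaving an exact 12-mer seed window for the aligner.
build_variant_table <- function(reference, max_tail = 3L) {
  mat <- reference$mature
  hp <- reference$hairpins
  out <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    m <- mat$sequence[i]
    L <- nchar(m)
    h <- hp[[mat$hairpin_id[i]]]
    mend <- mat$end[i]
    cont <- substr(h, mend + 1L, mend + max_tail)   # templated continuation
    cont_ch <- strsplit(cont, "", fixed = TRUE)[[1L]]

    rows <- list(
      data.frame(category = "canonical", offset5 = 0L, offset3 = 0L,
                 tail = "", subs = "", insert = m, stringsAsFactors = FALSE),
      data.frame(category = "trim5", offset5 = 1:2, offset3 = 0L, tail = "",
                 subs = "", insert = c(substr(m, 2L, L), substr(m, 3L, L)),
                 stringsAsFactors = FALSE),
      data.frame(category = "trim3", offset5 = 0L, offset3 = -(1:2), tail = "",
                 subs = "",
                 insert = c(substr(m, 1L, L - 1L), substr(m, 1L, L - 2L)),
                 stringsAsFactors = FALSE),
      data.frame(category = "ext3", offset5 = 0L, offset3 = 1:2, tail = "",
                 subs = "",
                 insert = c(paste0(m, cont_ch[1L]),
                            paste0(m, cont_ch[1L], cont_ch[2L])),
                 stringsAsFactors = FALSE))

    # non-templated tails: per position, bases from {A,T} differing from the
    # templated base (both allowed when the template is C or G)
    opts <- lapply(cont_ch, function(b) setdiff(c("A", "T"), b))
    tails <- unlist(lapply(seq_len(max_tail), function(len) {
      grid <- do.call(expand.grid,
                      c(opts[seq_len(len)], stringsAsFactors = FALSE))
      do.call(paste0, grid)
    }))
    rows[[length(rows) + 1L]] <-
      data.frame(category = "add3", offset5 = 0L, offset3 = 0L, tail = tails,
                 subs = "", insert = paste0(m, tails), stringsAsFactors = FALSE)

    p <- sample(4:8, 1L)
    ref_b <- substr(m, p, p)
    alt_b <- sample(setdiff(DNA_BASES, ref_b), 1L)
    sub_seq <- m
    substr(sub_seq, p, p) <- alt_b
    rows[[length(rows) + 1L]] <-
      data.frame(category = "subst", offset5 = 0L, offset3 = 0L, tail = "",
                 subs = sprintf("%d:%s>%s", p, ref_b, alt_b), insert = sub_seq,
                 stringsAsFactors = FALSE)

    v <- do.call(rbind, rows)
    v$mature_id <- mat$mature_id[i]
    out[[i]] <- v
  }
  vt <- do.call(rbind, out)
  vt$variant_id <- sprintf("%s|%d|%d|%s|%s", vt$mature_id, vt$offset5,
                           vt$offset3, vt$tail, vt$subs)
  rownames(vt) <- NULL
  vt[, c("variant_id", "mature_id", "category", "offset5", "offset3",
         "tail", "subs", "insert")]
}

#' Simulate isomiR-structured small-RNA reads from a count matrix
#'
#' For every (miRNA, sample) cell, emits exactly `count` reads. Each read is
#' drawn from the design's `isomir_profile`: canonical; 5' trim of 1-2 nt;
#' 3' trim of 1-2 nt; templated 3' extension of 1-2 nt copied from the
#' hairpin; a 1-3 nt non-templated 3' tail over \{A, T\} (every tail base
#' differs from the templated continuation); or an internal substitution at a
#' fixed per-miRNA mature position. The 3' adapter is appended, the read is
#' clipped to `read_length` cycles (padded with A beyond the adapter),
#' uniform sequencing errors are applied at `seq_error_rate`, and Phred+33
#' qualities are emitted with an occasional sub-Q20 trailing stretch.
#'
#' @param counts integer matrix, features x samples; rownames must equal the
#'   reference's mature ids.
#' @param reference a `mir_reference`.
#' @param design a [simulation_design()].
#' @param dir if non-NULL, per-sample FASTQ files are written there and file
#'   paths returned instead of in-memory reads.
#' @return list with `reads` (per-sample list of data.frames `id`,
#'   `sequence`, `quality`; NULL when `dir` is given), `files` (FASTQ paths
#'   or NULL) and `truth` (list: `variants`, the planted variant table, and
#'   `counts`, a variants x samples matrix of planted read counts).
#' @export
simulate_isomir_reads <- function(counts, reference, design, dir = NULL) {
  stopifnot(inherits(reference, "mir_reference"),
            inherits(design, "simulation_design"))
  ids <- reference$mature$mature_id
  if (is.null(rownames(counts)) || !setequal(rownames(counts), ids))
    stop("count matrix rows do not match the reference mature annotations")
  counts <- counts[ids, , drop = FALSE]
  set.seed(design$seed + 1L)
  vt <- build_variant_table(reference)
  nv <- nrow(vt)
  nf <- length(ids)
  samples <- colnames(counts)
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(ncol(counts)))

  # per-category row lookup into vt (rows of one miRNA are contiguous)
  cat_rows <- split(seq_len(nv), vt$mature_id)[ids]   # keep reference order
  row1 <- function(cat) vapply(cat_rows, function(r)
    r[vt$category[r] == cat][1L], 0L)
  rows_of <- function(cat) lapply(cat_rows, function(r)
    r[vt$category[r] == cat])
  canon_row <- row1("canonical")
  subst_row <- row1("subst")
  trim5_rows <- do.call(rbind, rows_of("trim5"))    # nf x 2
  trim3_rows <- do.call(rbind, rows_of("trim3"))
  ext3_rows <- do.call(rbind, rows_of("ext3"))
  add3_rows <- rows_of("add3")
  add3_start <- vapply(add3_rows, `[`, 0L, 1L)
  add3_n <- lengths(add3_rows)

  prof <- design$isomir_profile
  rl <- design$read_length
  pad <- paste0(design$adapter, strrep("A", rl))
  q_good <- strrep(rawToChar(as.raw(33L + 36L)), rl)            # Q36
  q_bad <- paste0(substr(q_good, 1L, rl - 3L),
                  strrep(rawToChar(as.raw(33L + 11L)), 3L))     # tail < Q20

  truth_counts <- matrix(0L, nv, length(samples),
                         dimnames = list(vt$variant_id, samples))
  reads <- if (is.null(dir)) vector("list", length(samples)) else NULL
  files <- if (!is.null(dir)) character(length(samples)) else NULL
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  for (j in seq_along(samples)) {
    cnt <- counts[, j]
    n_j <- sum(cnt)
    if (n_j == 0L) {
      if (is.null(dir)) {
        reads[[j]] <- data.frame(id = character(), sequence = character(),
                                 quality = character(),
                                 stringsAsFactors = FALSE)
      } else {
        files[j] <- file.path(dir, paste0(samples[j], ".fastq"))
        writeLines(character(), files[j])
      }
      next
    }
    mir <- rep.int(seq_len(nf), cnt)
    categ <- sample.int(6L, n_j, replace = TRUE, prob = prof)
    vrow <- integer(n_j)
    k <- categ == 1L; vrow[k] <- canon_row[mir[k]]
    k <- categ == 2L
    vrow[k] <- trim5_rows[cbind(mir[k], sample.int(2L, sum(k), TRUE))]
    k <- categ == 3L
    vrow[k] <- trim3_rows[cbind(mir[k], sample.int(2L, sum(k), TRUE))]
    k <- categ == 4L
    vrow[k] <- ext3_rows[cbind(mir[k], sample.int(2L, sum(k), TRUE))]
    k <- categ == 5L
    vrow[k] <- add3_start[mir[k]] +
      floor(stats::runif(sum(k)) * add3_n[mir[k]])
    k <- categ == 6L; vrow[k] <- subst_row[mir[k]]

    seqs <- substr(paste0(vt$insert[vrow], pad), 1L, rl)
    n_err <- stats::rbinom(n_j, rl, design$seq_error_rate)
    err_idx <- which(n_err > 0L)
    if (length(err_idx) > 0L) {
      seqs[err_idx] <- vapply(err_idx, function(r) {
        ch <- strsplit(seqs[r], "", fixed = TRUE)[[1L]]
        for (p in sample.int(rl, n_err[r]))
          ch[p] <- sample(DNA_BASES[DNA_BASES != ch[p]], 1L)
        paste(ch, collapse = "")
      }, "")
    }
    qual <- ifelse(stats::runif(n_j) < design$qual_degrade_prob, q_bad, q_good)
    rd <- data.frame(id = sprintf("%s_r%07d", samples[j], seq_len(n_j)),
                     sequence = seqs, quality = qual, stringsAsFactors = FALSE)
    truth_counts[, j] <- tabulate(vrow, nbins = nv)
    if (is.null(dir)) {
      reads[[j]] <- rd
    } else {
      files[j] <- file.path(dir, paste0(samples[j], ".fastq"))
      write_fastq(rd, files[j])
    }
  }
  if (is.null(dir)) names(reads) <- samples else names(files) <- samples
  list(reads = reads, files = files,
       truth = list(variants = vt, counts = truth_counts))
}
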