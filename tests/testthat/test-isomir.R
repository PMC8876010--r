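test_that("the k-mer index stores every hairpin window retrievably", {
  ref <- hand_reference()
  idx <- build_index(ref$hairpins, k = 12)
  hpB <- ref$hairpins[["hpB"]]
  # indexed window count for a single hairpin equals L - k + 1
  idx1 <- build_index(c(one = hpB), k = 12)
  total <- sum(vapply(ls(idx1$env), function(key) nrow(idx1$env[[key]]), 0L))
  expect_identical(total, nchar(hpB) - 11L)
  # a true window returns its (hairpin, offset)
  w <- substr(hpB, 7, 18)
  hit <- idx$env[[w]]
  expect_true(any(hit[, 1] == 2 & hit[, 2] == 7))
  # absent k-mer: empty
  expect_null(idx$env[["AAAAAAAAAAAA"]])
  expect_error(build_index(c(a = "ACGT", a = "ACGT")), "unique")
})

test_that("alignment finds all placements and flags unique best hits", {
  ref <- generate_reference(20, seed = 33)
  idx <- build_index(ref$hairpins)
  # canonical read: placed at its annotated locus with 0 substitutions
  m1 <- ref$mature[1, ]
  pl <- align_read(m1$sequence, idx)
  best <- pl[pl$n_subs == 0 & pl$tail_len == 0, ]
  expect_identical(nrow(best), 1L)
  expect_identical(best$hairpin_id, m1$hairpin_id)
  expect_identical(best$start, m1$start)
  expect_true(best$unique)

  # a 22-nt sequence planted into two hairpins: two placements, none unique
  rep22 <- "ACTGGTCAGGTTAACCGTACGA"
  hp2 <- c(x = paste0("GGGGG", rep22, "CCCCC"),
           y = paste0("TTTTT", rep22, "AAAAA"))
  pl2 <- align_read(rep22, build_index(hp2))
  pl2 <- pl2[pl2$n_subs == 0, ]
  expect_identical(sort(pl2$hairpin_id), c("x", "y"))
  expect_false(any(pl2$unique))

  # three substitutions exceed max_subs = 2
  r3 <- m1$sequence
  substr(r3, 3, 3) <- if (substr(r3, 3, 3) == "A") "C" else "A"
  substr(r3, 9, 9) <- if (substr(r3, 9, 9) == "A") "C" else "A"
  substr(r3, 15, 15) <- if (substr(r3, 15, 15) == "A") "C" else "A"
  pl3 <- align_read(r3, idx)
  expect_identical(nrow(pl3[pl3$hairpin_id == m1$hairpin_id &
                              pl3$start == m1$start, ]), 0L)
})

test_that("isomiR classification computes offsets, tails and substitutions", {
  ref <- hand_reference()
  idx <- build_index(ref$hairpins)
  mature <- ref$mature$sequence[1]   # hpA, flanked by GGGGG ... TTTTT
  classify_best <- function(read) {
    pl <- align_read(read, idx)
    pl <- pl[pl$n_subs == min(pl$n_subs), ][1, ]
    classify_isomir(read, pl, ref, idx)
  }
  canon <- classify_best(mature)
  expect_identical(canon[c("offset5", "offset3", "tail", "subs")],
                   list(offset5 = 0L, offset3 = 0L, tail = "", subs = ""))

  shift <- classify_best(substr(mature, 2, nchar(mature)))
  expect_identical(shift$offset5, 1L)          # seed shift by 5' trimming
  expect_identical(shift$offset3, 0L)

  # hairpin continues TT: an AA suffix is a non-templated tail ...
  tailed <- classify_best(paste0(mature, "AA"))
  expect_identical(tailed$tail, "AA")
  expect_identical(tailed$offset3, 0L)
  # ... whereas a TT suffix is a templated extension
  ext <- classify_best(paste0(mature, "TT"))
  expect_identical(ext$tail, "")
  expect_identical(ext$offset3, 2L)

  # internal mismatch recorded as a mature-relative substitution
  sub <- mature
  substr(sub, 5, 5) <- "G"   # position 5 is A in ACGTACGT...
  got <- classify_best(sub)
  expect_identical(got$subs, "5:A>G")
  expect_identical(got$offset5, 0L)

  # placement overlapping < 50% of the mature annotation: unassigned
  flank_read <- substr(ref$hairpins[["hpB"]], 1, 15)  # flank + 10 mature nt
  pl <- data.frame(hairpin_id = "hpB", start = 1L, n_subs = 0L,
                   tail_len = 0L, unique = TRUE)
  expect_null(classify_isomir(flank_read, pl, ref, idx))
})

test_that("read assignment conserves reads and round-trips planted calls", {
  sp <- small_pipeline()
  reads <- bind_reads(sp$rd$reads)
  pp <- preprocess_reads(reads, sp$design$adapter)
  prof <- profile_reads(pp$reads, sp$ref)
  # conservation: assigned + unassigned equals the preprocessed read count
  expect_identical(prof$stats$n_assigned + prof$stats$n_unassigned,
                   prof$stats$n_reads)
  expect_identical(sum(prof$stats$n_reads), nrow(pp$reads))
  # zero-error roundtrip: every planted call recovered exactly
  planted <- truth_long(sp$rd$truth)
  got <- prof$calls
  got$key <- call_keys(got)
  m <- merge(planted, got[, c("sample", "key", "count")],
             by = c("sample", "key"), all = TRUE)
  expect_false(anyNA(m$count.x))
  expect_false(anyNA(m$count.y))
  expect_identical(m$count.x, m$count.y)
})

test_that("substitution filters merge rare mismatches and drop multimapped ones", {
  calls <- data.frame(
    sample = "s1",
    mature_id = "mirA",
    offset5 = 0L, offset3 = 0L, tail = "",
    subs = c("", "5:C>T", "9:A>G"),
    unique = TRUE,
    count = c(60L, 30L, 10L),
    stringsAsFactors = FALSE)
  f <- apply_substitution_filters(calls)
  # 30/100 >= 0.25: retained; 10/100 < 0.25: merged into the clean call
  expect_identical(f$count[f$subs == "5:C>T"], 30L)
  expect_identical(f$count[f$subs == ""], 70L)
  expect_false("9:A>G" %in% f$subs)
  expect_identical(sum(f$count), 100L)

  # non-uniquely mapped substitution calls are discarded entirely
  calls$unique <- c(TRUE, FALSE, TRUE)
  f2 <- apply_substitution_filters(calls)
  expect_false("5:C>T" %in% f2$subs)
  expect_identical(sum(f2$count), 70L)

  # boundary: a fraction of exactly 0.25 is kept
  calls3 <- calls[1:2, ]
  calls3$unique <- TRUE
  calls3$count <- c(75L, 25L)
  expect_true("5:C>T" %in% apply_substitution_filters(calls3)$subs)
})

test_that("aggregation yields conserved miRNA and isomiR count matrices", {
  sp <- small_pipeline()
  reads <- bind_reads(sp$rd$reads)
  pp <- preprocess_reads(reads, sp$design$adapter)
  prof <- profile_reads(pp$reads, sp$ref)
  agg <- aggregate_counts(prof$calls, samples = sp$sim$metadata$sample_id)
  # per-sample miRNA column sums equal assigned reads
  expect_identical(as.integer(colSums(agg$mirna)[prof$stats$sample]),
                   prof$stats$n_assigned)
  # miRNA rows are the sums of their isomiR rows
  expect_equal(unname(rowsum(agg$isomir, agg$isomir_key$mature_id)),
               unname(agg$mirna), ignore_attr = TRUE)
  # a sample with no calls gets an all-zero column
  agg2 <- aggregate_counts(prof$calls[prof$calls$sample != "s001", ],
                           samples = sp$sim$metadata$sample_id)
  expect_identical(sum(agg2$mirna[, "s001"]), 0L)
})

test_that("modification profiles report per-position read fractions", {
  calls <- data.frame(
    sample = "s1", mature_id = "mirA",
    offset5 = c(0L, 0L, 1L, 0L),
    offset3 = c(0L, 0L, 0L, -1L),
    tail = c("", "A", "", ""),
    subs = "",
    unique = TRUE,
    count = c(500L, 250L, 150L, 100L),
    stringsAsFactors = FALSE)
  pr <- modification_profiles(calls)
  expect_equal(pr$abundance[pr$type == "3p_addition" & pr$position == 1],
               0.25)
  expect_equal(pr$abundance[pr$type == "5p_shift" & pr$position == 1], 0.15)
  expect_equal(pr$abundance[pr$type == "3p_trim" & pr$position == -1], 0.10)
  # scale invariance: duplicating every read leaves fractions unchanged
  calls2 <- calls
  calls2$count <- calls2$count * 2L
  expect_equal(modification_profiles(calls2)$abundance, pr$abundance)
  # all-canonical sample: nothing to report
  expect_identical(nrow(modification_profiles(calls[1, ])), 0L)
  # abundances lie in [0, 1] and per (sample, type) sums stay below 1
  sp <- small_pipeline()
  reads <- bind_reads(sp$rd$reads)
  pp <- preprocess_reads(reads, sp$design$adapter)
  fc <- apply_substitution_filters(profile_reads(pp$reads, sp$ref)$calls)
  pr2 <- modification_profiles(fc)
  expect_true(all(pr2$abundance >= 0 & pr2$abundance <= 1))
  sums <- tapply(pr2$abundance, paste(pr2$sample, pr2$type), sum)
  expect_true(all(sums <= 1 + 1e-12))
})
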