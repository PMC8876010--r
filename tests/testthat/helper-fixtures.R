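# hand-built reference for coordinate-level tests: mature between the bars of
# GGGGG | ACGTACGTACGTACGTACGTAC | TTTTT (and a second unrelated hairpin)
hand_reference <- function() {
  hairpins <- c(
    hpA = "GGGGGACGTACGTACGTACGTACGTACTTTTT",
    hpB = "CCCCCTTGACCTTGGAGCAATGCCAGTACCCCC")
  mature <- data.frame(
    hairpin_id = c("hpA", "hpB"),
    mature_id = c("hpA-mir", "hpB-mir"),
    start = c(6L, 6L),
    end = c(27L, 28L),
    stringsAsFactors = FALSE)
  mature$sequence <- substr(hairpins[mature$hairpin_id], mature$start,
                            mature$end)
  structure(list(hairpins = hairpins, mature = mature),
            class = "mir_reference")
}

# small end-to-end simulation shared across test files (computed lazily once)
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- simulation_design(n_hairpins = 15, n_samples_per_group = 3,
                             baseline_log2 = c(4, 6), seq_error_rate = 0,
                             seed = 11)
      ref <- generate_reference(d$n_hairpins, d$seed)
      sim <- simulate_counts(d, ref)
      rd <- simulate_isomir_reads(sim$counts, ref, d)
      cache <<- list(design = d, ref = ref, sim = sim, rd = rd)
    }
    cache
  }
})

# bind per-sample read list into one data.frame with a sample column
bind_reads <- function(read_list) {
  do.call(rbind, lapply(names(read_list), function(s) {
    x <- read_list[[s]]
    if (nrow(x) > 0L) x$sample <- s
    x
  }))
}

# planted isomiR truth as (sample, call-key, count) rows
truth_long <- function(truth) {
  out <- data.frame(
    sample = rep(colnames(truth$counts), each = nrow(truth$variants)),
    key = rep(truth$variants$variant_id, ncol(truth$counts)),
    count = as.vector(truth$counts), stringsAsFactors = FALSE)
  out[out$count > 0L, , drop = FALSE]
}

call_keys <- function(calls)
  sprintf("%s|%d|%d|%s|%s", calls$mature_id, calls$offset5, calls$offset3,
          calls$tail, calls$subs)
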