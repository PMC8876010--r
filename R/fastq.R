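#' Read a single-end FASTQ file (Phred+33)
#'
#' @param path FASTQ path (uncompressed or gzipped).
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns that FASTQ metadata columns are dropped; nothing is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)),
            all(nchar(reads$sequence) == nchar(reads$quality)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L)
    writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                      reads$quality), con)
  invisible(path)
}
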