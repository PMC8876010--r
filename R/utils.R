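#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Ordinal encoding of disease stage
#'
#' Encodes the healthy-adenoma-carcinoma sequence as ordinal values
#' HC = 0, AP = 1, CRC = 2.
#'
#' @param groups character or factor vector of group labels.
#' @return integer vector of the same length.
#' @export
stage_encoding <- function(groups) {
  enc <- c(HC = 0L, AP = 1L, CRC = 2L)
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), names(enc))
  if (length(bad) > 0L)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  unname(enc[groups])
}

# random DNA string(s)
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""), "")
}
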