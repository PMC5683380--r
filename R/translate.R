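
#' Reverse-complement a nucleotide string
#'
#' Complements A/C/G/T (N maps to N) and reverses the sequence. Used for
#' minus-strand coding sequence and junction-context extraction.
#'
#' @param nt A single nucleotide string (A/C/G/T/N, uppercase).
#' @return The reverse complement as a single string.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  if (nchar(nt) == 0L) return("")
  comp <- chartr("ACGTN", "TGCAN", nt)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate a nucleotide sequence
#'
#' Translates with the standard genetic code in the given frame. Codons that
#' contain any base other than A/C/G/T (typically N) yield `X`; a trailing
#' partial codon is dropped. With `truncate_at_stop = TRUE` the translation
#' ends before the first stop codon, otherwise stops appear as `*`.
#'
#' @param nt Nucleotide string over A/C/G/T/N.
#' @param frame Reading-frame offset, 0, 1 or 2 (bases skipped at the 5'
#'   end before the first codon).
#' @param truncate_at_stop Logical; stop translation at the first stop codon.
#' @return Amino-acid string (possibly empty).
#' @examples
#' translate_nt("ATGGCCTAA", frame = 0, truncate_at_stop = TRUE)  # "MA"
#' translate_nt("ATGGCC", frame = 1)                              # "W"
#' @export
translate_nt <- function(nt, frame = 0L, truncate_at_stop = FALSE) {
  stopifnot(is.character(nt), length(nt) == 1L)
  frame <- as.integer(frame)
  if (is.na(frame) || frame < 0L || frame > 2L)
    stop("`frame` must be 0, 1 or 2")
  n <- nchar(nt)
  if (n - frame < 3L) return("")
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(.CODON_TABLE[codons])
  aa[is.na(aa)] <- "X"
  if (truncate_at_stop) {
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  }
  paste(aa, collapse = "")
}
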