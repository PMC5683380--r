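#' Read an RSEM-style transcript abundance table
#'
#' Reads a TSV whose header contains `transcript_id` and `TPM` columns
#' (any further columns, e.g. `expected_count` or `FPKM`, are ignored).
#'
#' @param path TSV file.
#' @return Data frame with `transcript_id` and `TPM`.
#' @export
read_tpm_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "TPM")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing column(s) ", paste(missing_cols, collapse = ", "),
         "; available: ", paste(names(tab), collapse = ", "))
  out <- data.frame(transcript_id = as.character(tab$transcript_id),
                    TPM = as.numeric(tab$TPM),
                    stringsAsFactors = FALSE)
  dup <- unique(out$transcript_id[duplicated(out$transcript_id)])
  if (length(dup))
    stop("duplicate transcript id(s): ", paste(dup, collapse = ", "))
  if (any(is.na(out$TPM) | out$TPM < 0))
    stop("TPM values must be non-negative numbers")
  out
}

#' Reduce a reference entry stream by transcript abundance
#'
#' Retains a reference protein entry iff its transcript's abundance is at
#' least `threshold` TPM ("less than one TPM excluded": the boundary value
#' 1.0 is retained). Entries whose transcript has no abundance record are
#' treated as unquantified, excluded, and counted in the report attached
#' as the `"reduction"` attribute. Input order is preserved.
#'
#' @param entries `protein_entries` (the `REF` stream; SAV and SJ entries
#'   are already evidence-backed and are not reduced).
#' @param abundances Data frame from [read_tpm_table()].
#' @param threshold Minimum TPM retained (default 1.0).
#' @return The retained subset of `entries`, with a `"reduction"`
#'   attribute listing `kept`, `below_threshold` and `missing` counts.
#' @export
reduce_by_tpm <- function(entries, abundances, threshold = 1.0) {
  tx <- sub(";.*$", "", ifelse(nzchar(entries$provenance),
                               entries$provenance, entries$accession))
  tpm <- abundances$TPM[match(tx, abundances$transcript_id)]
  missing <- is.na(tpm)
  keep <- !missing & tpm >= threshold
  out <- entries[keep, , drop = FALSE]
  class(out) <- c("protein_entries", "data.frame")
  attr(out, "reduction") <- list(kept = sum(keep),
                                 below_threshold = sum(!missing & !keep),
                                 missing = sum(missing))
  out
}
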