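.ORIGINS <- c("REF", "SAV", "SJ", "DECOY")
.ORIGIN_TAGS <- c(REF = "ref", SAV = "sav", SJ = "sj")
.AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Construct a set of protein database entries
#'
#' The unit record of every search database: an accession, an amino-acid
#' sequence over the 20 standard residues, an origin stream (`REF`, `SAV`,
#' `SJ` or `DECOY`) and a structured provenance tag (transcript id; for SAV
#' additionally the substitution as `p.<Ref><Pos><Alt>`; for SJ the junction
#' key, frame and junction-spanning residue index).
#'
#' @param accession Character vector of unique accessions.
#' @param sequence Amino-acid sequences (no stop symbol, no `X`).
#' @param origin One of `"REF"`, `"SAV"`, `"SJ"`, `"DECOY"` (recycled).
#' @param provenance Structured provenance string (recycled, may be `""`).
#' @param description Free-text description (recycled, may be `""`).
#' @param target_origin For `DECOY` entries, the origin of the target entry
#'   the decoy reverses; `NA` otherwise.
#' @return A `protein_entries` data frame.
#' @examples
#' protein_entries("T1", "MKTAYIAK", "REF", provenance = "T1")
#' @export
protein_entries <- function(accession, sequence, origin = "REF",
                            provenance = "", description = "",
                            target_origin = NA_character_) {
  df <- data.frame(
    accession = as.character(accession),
    sequence = as.character(sequence),
    origin = rep_len(as.character(origin), length(accession)),
    provenance = rep_len(as.character(provenance), length(accession)),
    description = rep_len(as.character(description), length(accession)),
    target_origin = rep_len(as.character(target_origin), length(accession)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("protein_entries", "data.frame")
  validate_protein_entries(df)
  df
}

#' Validate protein entries
#'
#' Checks the entry invariants: non-empty sequences over the 20 standard
#' residues, unique accessions, known origins, SAV entries carrying exactly
#' one `p.` substitution tag and SJ entries carrying a junction key.
#'
#' @param entries A `protein_entries` data frame.
#' @return The entries, invisibly, if valid; otherwise an error.
#' @export
validate_protein_entries <- function(entries) {
  stopifnot(is.data.frame(entries))
  if (nrow(entries) == 0L) return(invisible(entries))
  bad_origin <- setdiff(unique(entries$origin), .ORIGINS)
  if (length(bad_origin))
    stop("unknown origin(s): ", paste(bad_origin, collapse = ", "))
  dup <- entries$accession[duplicated(entries$accession)]
  if (length(dup))
    stop("duplicate accession(s): ", paste(unique(dup), collapse = ", "))
  ok <- grepl(.AA_REGEX, entries$sequence)
  if (!all(ok))
    stop("invalid sequence for accession(s): ",
         paste(entries$accession[!ok], collapse = ", "))
  sav <- entries$origin == "SAV"
  n_tags <- lengths(regmatches(entries$provenance,
                               gregexpr("p\\.[A-Y][0-9]+[A-Y*]",
                                        entries$provenance)))
  if (any(sav & n_tags != 1L))
    stop("SAV entries must carry exactly one p.<Ref><Pos><Alt> tag: ",
         paste(entries$accession[sav & n_tags != 1L], collapse = ", "))
  sj <- entries$origin == "SJ"
  if (any(sj & !grepl(":[0-9]+-[0-9]+", entries$provenance)))
    stop("SJ entries must carry a junction key in their provenance")
  invisible(entries)
}

#' Read a genome FASTA file
#'
#' @param path FASTA file of nucleotide records.
#' @return Named character vector of uppercase sequences, one per
#'   chromosome, in file order.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(seqs))
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    stop("duplicate record name(s): ", paste(dup, collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- nms
  out
}

#' Write a genome FASTA file
#'
#' @param chromosomes Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(chromosomes, path) {
  x <- Biostrings::DNAStringSet(chromosomes)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.entry_header <- function(entries) {
  is_decoy <- entries$origin == "DECOY"
  tag <- ifelse(is_decoy,
                unname(.ORIGIN_TAGS[entries$target_origin]),
                unname(.ORIGIN_TAGS[entries$origin]))
  acc <- ifelse(is_decoy, sub("^DECOY_", "", entries$accession),
                entries$accession)
  hdr <- paste(tag, acc, entries$provenance, sep = "|")
  hdr <- ifelse(is_decoy, paste0("DECOY_", hdr), hdr)
  ifelse(nzchar(entries$description),
         paste(hdr, entries$description), hdr)
}

#' Write protein entries as FASTA
#'
#' Headers follow the grammar `>{origin-tag}|{accession}|{provenance}` with
#' origin-tag one of `ref`, `sav`, `sj`; decoy entries prepend `DECOY_` to
#' the full header. A write-read round trip is the identity on all fields.
#'
#' @param entries A `protein_entries` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(entries, path) {
  validate_protein_entries(entries)
  x <- Biostrings::AAStringSet(entries$sequence)
  names(x) <- .entry_header(entries)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a protein FASTA file written under the package header grammar
#'
#' @param path FASTA file path.
#' @return A `protein_entries` data frame.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  hdr <- names(x)
  desc <- sub("^\\S+\\s*", "", hdr)
  key <- sub("\\s.*$", "", hdr)
  is_decoy <- startsWith(key, "DECOY_")
  key2 <- sub("^DECOY_", "", key)
  parts <- strsplit(key2, "|", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("malformed header(s): ", paste(key[lengths(parts) < 2L], collapse = ", "))
  tag <- vapply(parts, `[`, "", 1L)
  acc <- vapply(parts, `[`, "", 2L)
  prov <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", "")
  origin_of_tag <- names(.ORIGIN_TAGS)[match(tag, .ORIGIN_TAGS)]
  if (anyNA(origin_of_tag))
    stop("unknown origin tag(s): ", paste(unique(tag[is.na(origin_of_tag)]),
                                          collapse = ", "))
  protein_entries(
    accession = ifelse(is_decoy, paste0("DECOY_", acc), acc),
    sequence = as.character(x),
    origin = ifelse(is_decoy, "DECOY", origin_of_tag),
    provenance = prov,
    description = desc,
    target_origin = ifelse(is_decoy, origin_of_tag, NA_character_)
  )
}
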