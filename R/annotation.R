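#' Assemble a genome annotation
#'
#' Binds chromosome sequences and gene models into the coordinate backbone
#' used by every translation step. All internal coordinates are 0-based
#' half-open; conversion from the 1-based inclusive GTF/GFF convention
#' happens in [read_gene_models()].
#'
#' @param chromosomes Named character vector of chromosome sequences, or
#'   `NULL` when only interval logic is needed.
#' @param genes List of gene records as returned by [read_gene_models()].
#' @return A `genome_annotation` object (list with `chromosomes`, `genes`
#'   and a flat transcript index).
#' @export
genome_annotation <- function(chromosomes = NULL, genes = list()) {
  tx <- list()
  for (g in genes) {
    stopifnot(g$strand %in% c("+", "-"))
    for (t in g$transcripts) {
      if (!is.null(chromosomes)) {
        L <- nchar(chromosomes[[t$chrom]])
        iv <- rbind(t$exons, t$cds)
        if (nrow(iv) && (min(iv[, 1L]) < 0L || max(iv[, 2L]) > L))
          stop("interval outside chromosome bounds for transcript ", t$id)
      }
      if (nrow(t$cds) > 1L) {
        o <- order(t$cds[, 1L])
        cds <- t$cds[o, , drop = FALSE]
        if (any(cds[-1L, 1L] < cds[-nrow(cds), 2L]))
          stop("overlapping CDS intervals in transcript ", t$id)
      }
      tx[[t$id]] <- t
    }
  }
  structure(list(chromosomes = chromosomes, genes = genes,
                 transcripts = tx),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s), %d gene(s), %d transcript(s)\n",
              length(x$chromosomes), length(x$genes), length(x$transcripts)))
  invisible(x)
}

.get_transcript <- function(annotation, transcript_id) {
  t <- annotation$transcripts[[transcript_id]]
  if (is.null(t)) stop("unknown transcript id: ", transcript_id)
  t
}

#' Read gene models from GTF or GFF3
#'
#' Imports exon and CDS features, groups them by transcript and converts
#' the file's 1-based inclusive coordinates to the internal 0-based
#' half-open convention. Exons are returned sorted by genomic start;
#' introns are derivable as the gaps between consecutive exons.
#'
#' @param path GTF or GFF3 file.
#' @param dialect `"gtf"` or `"gff3"`.
#' @return List of gene records; each gene has `id`, `strand` and a list of
#'   `transcripts` (each with `id`, `gene_id`, `chrom`, `strand`, `exons`
#'   and `cds` interval matrices, `frame`, `complete`).
#' @export
read_gene_models <- function(path, dialect = c("gtf", "gff3")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]; type <- type[keep]
  if (length(gr) == 0L) stop("no exon/CDS features in ", path)

  if (dialect == "gtf") {
    tx_id <- as.character(md$transcript_id)
    gene_id <- as.character(md$gene_id)
  } else {
    parent <- md$Parent
    tx_id <- sub("^transcript:", "", vapply(parent, function(p)
      if (length(p)) p[[1L]] else NA_character_, ""))
    gene_id <- if (!is.null(md$gene_id)) as.character(md$gene_id) else tx_id
  }
  if (anyNA(tx_id)) stop("feature without transcript assignment in ", path)

  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L   # 1-based inclusive -> 0-based half-open
  end0 <- GenomicRanges::end(gr)
  phase <- if (!is.null(md$phase)) suppressWarnings(as.integer(as.character(md$phase)))
           else rep(NA_integer_, length(gr))

  genes <- list()
  for (tid in unique(tx_id)) {
    i <- tx_id == tid
    st <- unique(strand[i])
    if (length(st) > 1L)
      stop("transcript ", tid, " has exons on mixed strands")
    if (!st %in% c("+", "-"))
      stop("transcript ", tid, " has no strand")
    ch <- unique(chrom[i])
    if (length(ch) > 1L) stop("transcript ", tid, " spans chromosomes")
    ex_i <- i & type == "exon"
    cds_i <- i & type == "CDS"
    exons <- cbind(start = start0[ex_i], end = end0[ex_i])
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    cds <- cbind(start = start0[cds_i], end = end0[cds_i])
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    if (nrow(exons) == 0L && nrow(cds) > 0L) exons <- cds
    # every CDS piece must lie inside some exon
    if (nrow(cds)) {
      inside <- vapply(seq_len(nrow(cds)), function(k)
        any(exons[, 1L] <= cds[k, 1L] & cds[k, 2L] <= exons[, 2L]), TRUE)
      if (!all(inside))
        stop("CDS interval outside its exon in transcript ", tid)
    }
    frame <- 0L
    if (nrow(cds) && any(cds_i)) {
      ph <- phase[cds_i][order(start0[cds_i])]
      first <- if (st == "+") 1L else length(ph)
      if (!is.na(ph[first])) frame <- ph[first]
    }
    cds_len <- if (nrow(cds)) sum(cds[, 2L] - cds[, 1L]) else 0L
    gid <- unique(gene_id[i])[1L]
    tx <- list(id = tid, gene_id = gid, chrom = ch, strand = st,
               exons = exons, cds = cds, frame = frame,
               complete = (frame == 0L && cds_len %% 3L == 0L))
    if (is.null(genes[[gid]]))
      genes[[gid]] <- list(id = gid, strand = st, transcripts = list())
    genes[[gid]]$transcripts[[tid]] <- tx
  }
  unname(genes)
}

#' Introns of an annotation
#'
#' Derives intron intervals (0-based half-open) as the gaps between
#' consecutive exons of each transcript.
#'
#' @param annotation A `genome_annotation` (or a gene list).
#' @return Data frame with `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`; one row per intron.
#' @export
annotation_introns <- function(annotation) {
  txs <- if (inherits(annotation, "genome_annotation"))
    annotation$transcripts
  else unlist(lapply(annotation, `[[`, "transcripts"), recursive = FALSE)
  out <- lapply(txs, function(t) {
    ex <- t$exons
    if (nrow(ex) < 2L) return(NULL)
    data.frame(chrom = t$chrom,
               start = ex[-nrow(ex), 2L],
               end = ex[-1L, 1L],
               strand = t$strand,
               transcript_id = t$id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      transcript_id = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the CDS pieces in genomic order and, for minus-strand
#' transcripts, reverse-complements the concatenated sequence as one unit,
#' so the result reads in transcription order.
#'
#' @param annotation A `genome_annotation` with chromosome sequences.
#' @param transcript_id Transcript identifier.
#' @return Nucleotide string of the spliced CDS.
#' @export
spliced_cds_sequence <- function(annotation, transcript_id) {
  t <- .get_transcript(annotation, transcript_id)
  if (nrow(t$cds) == 0L) stop("transcript has no CDS: ", transcript_id)
  chrom <- annotation$chromosomes[[t$chrom]]
  if (is.null(chrom)) stop("unknown chromosome: ", t$chrom)
  pieces <- substring(chrom, t$cds[, 1L] + 1L, t$cds[, 2L])
  nt <- paste(pieces, collapse = "")
  if (t$strand == "-") nt <- reverse_complement(nt)
  nt
}

#' Reference protein entries from an annotation
#'
#' Translates every coding transcript (spliced CDS, transcript frame,
#' truncated at the first stop) into one `REF` protein entry, accessioned
#' by transcript id. This is the reference proteome stream that the
#' abundance-reduction step filters.
#'
#' @param annotation A `genome_annotation` with chromosome sequences.
#' @return A `protein_entries` data frame with `origin = "REF"`.
#' @export
reference_entries <- function(annotation) {
  ids <- names(annotation$transcripts)
  ids <- ids[vapply(annotation$transcripts, function(t) nrow(t$cds) > 0L, TRUE)]
  prot <- vapply(ids, function(id) {
    t <- annotation$transcripts[[id]]
    translate_nt(spliced_cds_sequence(annotation, id), frame = t$frame,
                 truncate_at_stop = TRUE)
  }, "")
  keep <- nzchar(prot) & grepl(.AA_REGEX, prot)
  if (any(!keep))
    warning("dropped ", sum(!keep),
            " transcript(s) with empty or ambiguous translation")
  protein_entries(accession = ids[keep], sequence = unname(prot[keep]),
                  origin = "REF", provenance = ids[keep])
}
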