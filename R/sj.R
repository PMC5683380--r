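#' Read splice-junction evidence from a BED12 file
#'
#' Consumes TopHat-style `junctions.bed` records: each record has exactly
#' two blocks (the aligned flanks), and the intron is the gap between them:
#' `[chromStart + blockSize1, chromStart + blockStart2)` in 0-based
#' half-open coordinates. The score column is kept as the supporting read
#' count and the strand column is preserved (`.` meaning unknown).
#'
#' @param path BED12 file.
#' @return Data frame with `chrom`, `intron_start`, `intron_end`, `strand`,
#'   `left_flank`, `right_flank`, `read_count`, `name`.
#' @export
read_junction_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  blocks <- md$blocks
  if (is.null(blocks)) stop("not a BED12 file (no block structure): ", path)
  nb <- lengths(blocks)
  bad <- which(nb != 2L)
  if (length(bad))
    stop("record ", bad[1L], ": expected 2 blocks, found ", nb[bad[1L]])
  chrom_start0 <- GenomicRanges::start(gr) - 1L
  b1_width <- vapply(seq_along(gr), function(i)
    IRanges::width(blocks[[i]])[1L], 0L)
  b2_rel0 <- vapply(seq_along(gr), function(i)
    IRanges::start(blocks[[i]])[2L] - 1L, 0L)
  b2_width <- vapply(seq_along(gr), function(i)
    IRanges::width(blocks[[i]])[2L], 0L)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    intron_start = chrom_start0 + b1_width,
    intron_end = chrom_start0 + b2_rel0,
    strand = strand,
    left_flank = b1_width,
    right_flank = b2_width,
    read_count = if (!is.null(md$score)) as.integer(md$score) else NA_integer_,
    name = if (!is.null(md$name)) as.character(md$name) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(out$intron_end <= out$intron_start))
    stop("degenerate intron (length < 1) in record ",
         which(out$intron_end <= out$intron_start)[1L])
  out
}

#' Detect junctions absent from the gene model
#'
#' A junction is annotated iff its (chromosome, intron start, intron end)
#' exactly matches an intron of the annotation; strand is compared only
#' when both the junction and the annotation record a strand. Returns the
#' unannotated complement in stable input order.
#'
#' @param junctions Junction data frame from [read_junction_bed()].
#' @param annotation A `genome_annotation` (or gene list).
#' @return The subset of `junctions` not matching any annotated intron.
#' @export
detect_novel_junctions <- function(junctions, annotation) {
  introns <- annotation_introns(annotation)
  coord_key <- function(chrom, s, e) paste(chrom, s, e, sep = ":")
  ann_coord <- coord_key(introns$chrom, introns$start, introns$end)
  ann_stranded <- paste(ann_coord, introns$strand)
  j_coord <- coord_key(junctions$chrom, junctions$intron_start,
                       junctions$intron_end)
  known_strand <- junctions$strand %in% c("+", "-")
  annotated <- ifelse(known_strand,
                      paste(j_coord, junctions$strand) %in% ann_stranded,
                      j_coord %in% ann_coord)
  junctions[!annotated, , drop = FALSE]
}

#' Translate a splice junction into search-database polypeptides
#'
#' Extracts up to `flank_nt` bases on each side of the intron (capped by
#' the junction's aligned flank lengths), splices them, and translates in
#' three frames -- on both strands when the junction strand is unknown;
#' minus-strand context is reverse-complemented first. Each frame's
#' translation is split at stop codons, and only segments that span the
#' junction point with at least one residue contributed by each side, have
#' no ambiguous residue, and reach `min_length` residues are emitted. The
#' provenance records the junction key, orientation, frame and the
#' junction-spanning residue pair within the entry.
#'
#' @param junction One-row junction data frame.
#' @param genome Named character vector of chromosome sequences.
#' @param flank_nt Maximum flank length in nucleotides per side (default 66
#'   nt, i.e. up to 22 residues per side, enough for fully tryptic
#'   peptides with two missed cleavages).
#' @param min_length Minimum retained segment length in residues (the
#'   search engine's minimum peptide length).
#' @return A `protein_entries` data frame with `origin = "SJ"`.
#' @export
junction_entries <- function(junction, genome, flank_nt = 66L,
                             min_length = 6L) {
  stopifnot(flank_nt >= 3L)
  chrom <- genome[[junction$chrom]]
  if (is.null(chrom)) stop("unknown chromosome: ", junction$chrom)
  L_chr <- nchar(chrom)
  s <- as.integer(junction$intron_start)
  e <- as.integer(junction$intron_end)
  if (s < 0L || e > L_chr) stop("junction outside chromosome bounds")
  left_len <- min(flank_nt, junction$left_flank, s)
  right_len <- min(flank_nt, junction$right_flank, L_chr - e)
  if (left_len < 1L || right_len < 1L)
    return(protein_entries(character(), character(), origin = "SJ"))
  left <- substr(chrom, s - left_len + 1L, s)
  right <- substr(chrom, e + 1L, e + right_len)

  orientations <- if (junction$strand %in% c("+", "-")) junction$strand
                  else c("+", "-")
  key <- sprintf("%s:%d-%d(%s)", junction$chrom, s, e, junction$strand)

  acc <- seqs <- prov <- character()
  for (ori in orientations) {
    ctx <- paste0(left, right)
    jpoint <- left_len                    # nt index (0-based) of first right base
    if (ori == "-") {
      ctx <- reverse_complement(ctx)
      jpoint <- right_len
    }
    for (frame in 0:2) {
      aa <- translate_nt(ctx, frame = frame)
      if (!nchar(aa)) next
      # split at stops, tracking residue coordinates in the frame translation
      res <- strsplit(aa, "", fixed = TRUE)[[1L]]
      seg_start <- 1L
      segi <- 0L
      for (k in c(which(res == "*"), length(res) + 1L)) {
        if (k > seg_start) {
          seg <- seq.int(seg_start, k - 1L)
          # nt range covered by residue r: [frame + (r-1)*3, frame + r*3)
          first_nt <- frame + (seg - 1L) * 3L
          last_nt <- frame + seg * 3L - 1L
          has_left <- first_nt < jpoint
          has_right <- last_nt >= jpoint
          if (any(has_left) && any(has_right)) {
            span_a <- max(seg[has_left])
            span_b <- min(seg[has_right])
            pep <- paste(res[seg], collapse = "")
            if (nchar(pep) >= min_length && grepl(.AA_REGEX, pep)) {
              segi <- segi + 1L
              i_in <- span_a - seg[1L] + 1L
              j_in <- span_b - seg[1L] + 1L
              acc <- c(acc, sprintf("SJ_%s_%d_%d_%s_f%d_%d",
                                    junction$chrom, s, e, ori, frame,
                                    length(acc) + 1L))
              seqs <- c(seqs, pep)
              prov <- c(prov, sprintf("%s;ori=%s;frame=%d;span=%d-%d",
                                      key, ori, frame, i_in, j_in))
            }
          }
        }
        seg_start <- k + 1L
      }
    }
  }
  if (!length(acc))
    return(protein_entries(character(), character(), origin = "SJ"))
  protein_entries(accession = acc, sequence = seqs, origin = "SJ",
                  provenance = prov)
}

#' Translate many junctions into one SJ entry stream
#'
#' @param junctions Junction data frame (typically the output of
#'   [detect_novel_junctions()]).
#' @inheritParams junction_entries
#' @return A `protein_entries` data frame with `origin = "SJ"`.
#' @export
junction_db <- function(junctions, genome, flank_nt = 66L, min_length = 6L) {
  out <- lapply(seq_len(nrow(junctions)), function(i)
    junction_entries(junctions[i, , drop = FALSE], genome,
                     flank_nt = flank_nt, min_length = min_length))
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L)
    return(protein_entries(character(), character(), origin = "SJ"))
  class(out) <- c("protein_entries", "data.frame")
  validate_protein_entries(out)
  out
}

#' Parse an SJ provenance tag
#'
#' @param provenance SJ provenance strings.
#' @return Data frame with `chrom`, `intron_start`, `intron_end`, `strand`,
#'   `orientation`, `frame`, `span_from`, `span_to` (the junction-spanning
#'   residue pair, 1-based within the entry).
#' @export
parse_sj_tag <- function(provenance) {
  provenance <- sub(",.*$", "", provenance)  # merged provenance: first tag
  pat <- "^([^:]+):([0-9]+)-([0-9]+)\\(([+.-])\\);ori=([+-]);frame=([0-2]);span=([0-9]+)-([0-9]+)$"
  m <- regmatches(provenance, regexec(pat, provenance))
  bad <- lengths(m) != 9L
  if (any(bad)) stop("malformed SJ provenance: ",
                     paste(provenance[bad], collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2L),
             intron_start = as.integer(vapply(m, `[`, "", 3L)),
             intron_end = as.integer(vapply(m, `[`, "", 4L)),
             strand = vapply(m, `[`, "", 5L),
             orientation = vapply(m, `[`, "", 6L),
             frame = as.integer(vapply(m, `[`, "", 7L)),
             span_from = as.integer(vapply(m, `[`, "", 8L)),
             span_to = as.integer(vapply(m, `[`, "", 9L)),
             stringsAsFactors = FALSE)
}
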