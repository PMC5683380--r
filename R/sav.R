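#' Read single-nucleotide variant calls from a VCF file
#'
#' Consumes CHROM, POS, REF and ALT of a VCF v4.x file. Multi-allelic
#' records are split into one call per alternate allele; records that are
#' not single-nucleotide substitutions (indels, MNVs) are dropped with a
#' message. Positions are converted from the VCF's 1-based convention to
#' the internal 0-based coordinate.
#'
#' @param path VCF file.
#' @param sample Sample identifier attached to every call.
#' @return Data frame with `chrom`, `pos` (0-based), `ref`, `alt`, `sample`.
#' @export
read_vcf_calls <- function(path, sample = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), sample = character(),
                      stringsAsFactors = FALSE))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  out <- data.frame(chrom = fix$CHROM[idx],
                    pos = as.integer(fix$POS[idx]) - 1L,
                    ref = toupper(fix$REF[idx]),
                    alt = toupper(unlist(alts)),
                    sample = sample,
                    stringsAsFactors = FALSE)
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  if (any(!snv))
    message("dropped ", sum(!snv), " non-SNV record(s)")
  out[snv, , drop = FALSE]
}

.complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Classify the coding effect of a single-nucleotide variant
#'
#' Locates the variant in every overlapping transcript's CDS and derives
#' the codon change, strand-aware: for minus-strand transcripts the
#' alternate base is complemented before substitution. Variants outside
#' all CDS yield a single `noncoding` effect.
#'
#' @param annotation A `genome_annotation` with chromosome sequences.
#' @param variant One-row data frame (or list) with `chrom`, `pos`
#'   (0-based), `ref`, `alt`.
#' @return Data frame of effects, one row per overlapping transcript (or
#'   one `noncoding` row): transcript id, CDS offset, codon index,
#'   ref/alt codon, ref/alt residue and `category` in
#'   `synonymous`, `nonsynonymous`, `stop_gain`, `stop_loss`, `noncoding`.
#' @export
classify_variant_effect <- function(annotation, variant) {
  chrom_seq <- annotation$chromosomes[[variant$chrom]]
  if (is.null(chrom_seq)) stop("unknown chromosome: ", variant$chrom)
  pos <- as.integer(variant$pos)
  genome_base <- substr(chrom_seq, pos + 1L, pos + 1L)
  if (genome_base != variant$ref)
    stop(sprintf("ref base mismatch at %s:%d: VCF says %s, genome has %s",
                 variant$chrom, pos, variant$ref, genome_base))

  noncoding <- data.frame(
    chrom = variant$chrom, pos = pos, ref = variant$ref, alt = variant$alt,
    transcript_id = NA_character_, cds_offset = NA_integer_,
    codon_index = NA_integer_, ref_codon = NA_character_,
    alt_codon = NA_character_, ref_residue = NA_character_,
    alt_residue = NA_character_, category = "noncoding",
    stringsAsFactors = FALSE)

  rows <- list()
  for (t in annotation$transcripts) {
    if (t$chrom != variant$chrom || nrow(t$cds) == 0L) next
    hit <- which(t$cds[, 1L] <= pos & pos < t$cds[, 2L])
    if (!length(hit)) next
    # offset of the variant base within the spliced CDS, in transcription order
    plus_offset <- sum(t$cds[seq_len(hit - 1L), 2L] - t$cds[seq_len(hit - 1L), 1L]) +
      (pos - t$cds[hit, 1L])
    total <- sum(t$cds[, 2L] - t$cds[, 1L])
    cds_offset <- if (t$strand == "+") plus_offset else total - 1L - plus_offset
    eff_offset <- cds_offset - t$frame
    if (eff_offset < 0L) next
    codon_index <- eff_offset %/% 3L
    pos_in_codon <- eff_offset %% 3L
    cds_nt <- spliced_cds_sequence(annotation, t$id)
    codon_start <- t$frame + codon_index * 3L
    if (codon_start + 3L > nchar(cds_nt)) next  # partial trailing codon
    ref_codon <- substr(cds_nt, codon_start + 1L, codon_start + 3L)
    alt_base <- if (t$strand == "+") variant$alt else .complement_base(variant$alt)
    alt_codon <- ref_codon
    substr(alt_codon, pos_in_codon + 1L, pos_in_codon + 1L) <- alt_base
    ref_res <- translate_nt(ref_codon)
    alt_res <- translate_nt(alt_codon)
    category <-
      if (ref_res == alt_res && ref_res != "*") "synonymous"
      else if (ref_res == "*" && alt_res != "*") "stop_loss"
      else if (alt_res == "*" && ref_res != "*") "stop_gain"
      else "nonsynonymous"
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = variant$chrom, pos = pos, ref = variant$ref, alt = variant$alt,
      transcript_id = t$id, cds_offset = cds_offset,
      codon_index = codon_index, ref_codon = ref_codon,
      alt_codon = alt_codon, ref_residue = ref_res, alt_residue = alt_res,
      category = category, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(noncoding)
  do.call(rbind, rows)
}

#' Classify a table of variant calls
#'
#' @param annotation A `genome_annotation`.
#' @param variants Data frame of calls as from [read_vcf_calls()].
#' @return Row-bound effects of [classify_variant_effect()] per call.
#' @export
classify_variant_effects <- function(annotation, variants) {
  out <- lapply(seq_len(nrow(variants)), function(i)
    classify_variant_effect(annotation, variants[i, , drop = FALSE]))
  do.call(rbind, out)
}

#' Build single amino acid variant (SAV) protein entries
#'
#' Emits one full-length variant protein per nonsynonymous effect: the
#' reference protein with the single substitution applied, tagged
#' `p.<Ref><Pos><Alt>` (1-based residue position). Synonymous and
#' noncoding effects emit nothing; stop-gain effects emit the truncated
#' protein when it reaches the minimum length; stop-loss effects are
#' skipped (the extension is undefined without a 3' sequence policy).
#' Duplicate (transcript, substitution) pairs are deduplicated.
#'
#' @param effects Effect table from [classify_variant_effects()].
#' @param reference_proteome `protein_entries` holding the `REF` proteins,
#'   accessioned by transcript id.
#' @param min_length Minimum protein length retained for stop-gain
#'   truncations (residues).
#' @return A `protein_entries` data frame with `origin = "SAV"`.
#' @export
build_sav_entries <- function(effects, reference_proteome, min_length = 6L) {
  prot <- stats::setNames(reference_proteome$sequence,
                          reference_proteome$accession)
  acc <- seqs <- prov <- character()
  use <- effects[!is.na(effects$category) &
                   effects$category %in% c("nonsynonymous", "stop_gain",
                                           "stop_loss"), , drop = FALSE]
  for (i in seq_len(nrow(use))) {
    e <- use[i, ]
    if (e$category == "stop_loss") {
      message("skipping stop_loss variant in ", e$transcript_id)
      next
    }
    p <- unname(prot[match(e$transcript_id, names(prot))])
    if (is.na(p)) stop("unknown transcript in effects: ", e$transcript_id)
    res_pos <- e$codon_index + 1L
    if (res_pos > nchar(p)) {
      warning("variant beyond translated protein in ", e$transcript_id,
              "; skipped")
      next
    }
    if (substr(p, res_pos, res_pos) != e$ref_residue)
      stop("reference residue mismatch for ", e$transcript_id,
           " position ", res_pos)
    if (e$category == "nonsynonymous") {
      v <- p
      substr(v, res_pos, res_pos) <- e$alt_residue
      tag <- sprintf("p.%s%d%s", e$ref_residue, res_pos, e$alt_residue)
    } else {  # stop_gain
      v <- substr(p, 1L, res_pos - 1L)
      if (nchar(v) < min_length) next
      tag <- sprintf("p.%s%d*", e$ref_residue, res_pos)
    }
    acc <- c(acc, sprintf("SAV_%s_%s", e$transcript_id, tag))
    seqs <- c(seqs, v)
    prov <- c(prov, sprintf("%s;%s", e$transcript_id, tag))
  }
  keep <- !duplicated(acc)
  if (!length(acc))
    return(protein_entries(character(), character(), origin = "SAV"))
  protein_entries(accession = acc[keep], sequence = seqs[keep],
                  origin = "SAV", provenance = prov[keep])
}

#' Parse a SAV provenance tag
#'
#' @param provenance SAV provenance strings (`"<transcript>;p.<Ref><Pos><Alt>"`).
#' @return Data frame with `transcript_id`, `ref_residue`, `position`
#'   (1-based), `alt_residue`.
#' @export
parse_sav_tag <- function(provenance) {
  provenance <- sub(",.*$", "", provenance)  # merged provenance: first tag
  m <- regmatches(provenance,
                  regexec("^([^;]+);p\\.([A-Y])([0-9]+)([A-Y*])$", provenance))
  bad <- lengths(m) != 5L
  if (any(bad)) stop("malformed SAV provenance: ",
                     paste(provenance[bad], collapse = ", "))
  data.frame(transcript_id = vapply(m, `[`, "", 2L),
             ref_residue = vapply(m, `[`, "", 3L),
             position = as.integer(vapply(m, `[`, "", 4L)),
             alt_residue = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}
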