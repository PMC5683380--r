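.random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# map a spliced-CDS offset (0-based, transcription order) to a genomic position
.cds_offset_to_genomic <- function(tx, offset) {
  lens <- tx$cds[, 2L] - tx$cds[, 1L]
  plus_offset <- if (tx$strand == "+") offset else sum(lens) - 1L - offset
  piece <- findInterval(plus_offset, cumsum(c(0L, lens)),
                        rightmost.closed = FALSE)
  tx$cds[piece, 1L] + (plus_offset - sum(lens[seq_len(piece - 1L)]))
}

#' Simulate a toy genome with multi-exon genes
#'
#' Generates one chromosome carrying `n_genes` multi-exon genes on both
#' strands. Every coding sequence is ATG-initiated, free of internal
#' stops, and terminated by a stop codon held in the last exon (exons
#' include the stop codon; CDS excludes it, as in Ensembl GTF). Exon
#' boundaries fall on codon boundaries, so skipping any internal exon
#' preserves the reading frame -- the junction mechanism the sample
#' simulator plants. Deterministic under `seed`.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param exons_per_gene Exons per transcript (>= 2).
#' @param seed Integer seed.
#' @param codons_per_gene Range (min, max) of codons per CDS.
#' @param intron_length Range of intron lengths (nt).
#' @param dir Optional directory; when given, `genome.fasta` and
#'   `annotation.gtf` are written there.
#' @return A `synthetic_truth` list: `genome` (named chromosome vector),
#'   `annotation` (a `genome_annotation`), `proteins` (named reference
#'   translations), and the written paths when `dir` is given.
#' @export
simulate_genome_and_truth <- function(n_genes = 20L, exons_per_gene = 3L,
                                      seed = 1L,
                                      codons_per_gene = c(60L, 160L),
                                      intron_length = c(60L, 200L),
                                      dir = NULL) {
  stopifnot(n_genes >= 1L, exons_per_gene >= 2L)
  set.seed(seed)
  chrom_parts <- character()
  pos <- 0L
  genes <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("G%03d", g)
    tid <- sprintf("T%03d", g)
    strand <- sample(c("+", "-"), 1L)
    n_cod <- sample(seq(codons_per_gene[1L], codons_per_gene[2L]), 1L)
    coding <- paste0("ATG",
                     paste(sample(.SENSE_CODONS, n_cod - 1L, replace = TRUE),
                           collapse = ""),
                     sample(.STOP_CODONS, 1L))
    total_nt <- nchar(coding)                  # 3*n_cod + 3, incl. stop
    total_cod <- total_nt %/% 3L
    # split into exons at codon boundaries; every piece >= 12 codons
    min_cod <- 12L
    repeat {
      cuts <- sort(sample(seq(min_cod, total_cod - min_cod), exons_per_gene - 1L))
      lens_cod <- diff(c(0L, cuts, total_cod))
      if (all(lens_cod >= min_cod)) break
    }
    piece_len <- lens_cod * 3L
    introns <- vapply(seq_len(exons_per_gene - 1L), function(i) {
      body <- .random_nt(sample(seq(intron_length[1L], intron_length[2L]), 1L) - 4L)
      paste0("GT", body, "AG")
    }, "")
    # fragment in transcription order
    frag <- character(2L * exons_per_gene - 1L)
    frag[seq(1L, length(frag), 2L)] <- substring(
      coding, cumsum(c(0L, piece_len[-exons_per_gene])) + 1L,
      cumsum(piece_len))
    frag[seq(2L, length(frag), 2L)] <- introns
    frag_seq <- paste(frag, collapse = "")
    F <- nchar(frag_seq)
    # transcript-orientation offsets of the exon pieces within the fragment
    part_len <- nchar(frag)
    part_end <- cumsum(part_len)
    part_start <- part_end - part_len
    exon_fa <- part_start[seq(1L, length(frag), 2L)]
    exon_fb <- part_end[seq(1L, length(frag), 2L)]
    if (strand == "-") {
      frag_seq <- reverse_complement(frag_seq)
      tmp <- F - exon_fb
      exon_fb <- F - exon_fa
      exon_fa <- tmp
      o <- order(exon_fa)
      exon_fa <- exon_fa[o]; exon_fb <- exon_fb[o]
    }
    spacer <- .random_nt(sample(200:400, 1L))
    chrom_parts <- c(chrom_parts, spacer, frag_seq)
    gstart <- pos + nchar(spacer)
    pos <- gstart + F
    exons <- cbind(start = gstart + exon_fa, end = gstart + exon_fb)
    # CDS = exons minus the 3-nt stop codon at the transcription 3' end
    cds <- exons
    if (strand == "+") cds[nrow(cds), 2L] <- cds[nrow(cds), 2L] - 3L
    else cds[1L, 1L] <- cds[1L, 1L] + 3L
    tx <- list(id = tid, gene_id = gid, chrom = "chr1", strand = strand,
               exons = exons, cds = cds, frame = 0L, complete = TRUE)
    genes[[gid]] <- list(id = gid, strand = strand,
                         transcripts = stats::setNames(list(tx), tid))
  }
  chrom_parts <- c(chrom_parts, .random_nt(200L))
  genome <- c(chr1 = paste(chrom_parts, collapse = ""))
  annotation <- genome_annotation(genome, unname(genes))
  proteins <- vapply(names(annotation$transcripts), function(id)
    translate_nt(spliced_cds_sequence(annotation, id), truncate_at_stop = TRUE),
    "")
  truth <- structure(list(genome = genome, annotation = annotation,
                          proteins = proteins, seed = seed),
                     class = "synthetic_truth")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    truth$genome_fasta <- file.path(dir, "genome.fasta")
    write_genome_fasta(genome, truth$genome_fasta)
    truth$gtf <- file.path(dir, "annotation.gtf")
    write_gtf(annotation, truth$gtf)
  }
  truth
}

#' Write an annotation as GTF
#'
#' Exon and CDS features, 1-based inclusive, with CDS phase.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  lines <- character()
  for (tx in annotation$transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id, tx$id)
    for (i in seq_len(nrow(tx$exons)))
      lines <- c(lines, paste(tx$chrom, "sim", "exon",
                              tx$exons[i, 1L] + 1L, tx$exons[i, 2L],
                              ".", tx$strand, ".", attrs, sep = "\t"))
    if (nrow(tx$cds)) {
      ord <- if (tx$strand == "+") seq_len(nrow(tx$cds))
             else rev(seq_len(nrow(tx$cds)))
      lens <- tx$cds[, 2L] - tx$cds[, 1L]
      prior <- cumsum(c(0L, lens[ord]))[seq_along(ord)]
      phase <- (3L - prior %% 3L) %% 3L
      for (k in seq_along(ord)) {
        i <- ord[k]
        lines <- c(lines, paste(tx$chrom, "sim", "CDS",
                                tx$cds[i, 1L] + 1L, tx$cds[i, 2L],
                                ".", tx$strand, phase[k], attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate per-sample RNA-Seq evidence with a truth manifest
#'
#' Plants nonsynonymous and synonymous SNVs at sampled CDS positions (the
#' intended codon effect is verified at generation time), creates novel
#' junctions by exon skipping (annotated donor of exon *i* joined to the
#' annotated acceptor of exon *i+2*), and draws transcript abundances
#' with an exact fraction of transcripts below 1 TPM (one transcript is
#' pinned at exactly 1.0 to exercise the boundary). Annotated junctions
#' are emitted alongside the novel ones so novelty detection is
#' non-trivial. Outputs are a VCF, a two-block BED12 and an RSEM-style
#' TSV, all of which pass the package readers' validation.
#'
#' @param truth A `synthetic_truth` from [simulate_genome_and_truth()].
#' @param n_nssnp,n_syn Numbers of nonsynonymous / synonymous SNVs.
#' @param n_novel_junctions Number of exon-skipping junctions (requires
#'   transcripts with >= 3 exons).
#' @param tpm_params List with `meanlog`, `sdlog` (log-normal body for
#'   expressed transcripts) and `frac_below_1` (exact fraction of
#'   transcripts drawn below 1 TPM).
#' @param seed Integer seed.
#' @param dir Directory for `sample.vcf`, `junctions.bed`,
#'   `abundance.tsv` (created if needed).
#' @param sample Sample identifier.
#' @param bed_flank Aligned flank length written to the BED blocks (nt,
#'   capped by exon lengths).
#' @return List with the written paths and the truth tables: `snvs`
#'   (position, alleles, transcript, expected `p.` tag, category),
#'   `novel_junctions` (intron coordinates, skipped exon, expected
#'   in-frame junction peptide and spanning residue pair), `tpm`
#'   (per-transcript abundances).
#' @export
simulate_sample_evidence <- function(truth, n_nssnp = 10L, n_syn = 5L,
                                     n_novel_junctions = 5L,
                                     tpm_params = list(meanlog = log(20),
                                                       sdlog = 1.5,
                                                       frac_below_1 = 0.3),
                                     seed = 1L, dir = tempfile("evidence"),
                                     sample = "S1", bed_flank = 48L) {
  set.seed(seed)
  ann <- truth$annotation
  genome <- truth$genome
  txs <- ann$transcripts
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- SNVs ----------------------------------------------------------
  plant_snv <- function(want_nonsyn, used_pos, used_codon) {
    for (attempt in 1:500) {
      tx <- txs[[sample(names(txs), 1L)]]
      n_cod <- sum(tx$cds[, 2L] - tx$cds[, 1L]) %/% 3L
      codon_i <- sample(seq(1L, n_cod - 1L), 1L)     # skip the start codon
      codon_key <- paste(tx$id, codon_i)
      if (codon_key %in% used_codon) next
      cds_nt <- spliced_cds_sequence(ann, tx$id)
      codon <- substr(cds_nt, codon_i * 3L + 1L, codon_i * 3L + 3L)
      pic <- sample(0:2, 1L)
      ref_cds_base <- substr(codon, pic + 1L, pic + 1L)
      alt_cds_base <- sample(setdiff(c("A", "C", "G", "T"), ref_cds_base), 1L)
      alt_codon <- codon
      substr(alt_codon, pic + 1L, pic + 1L) <- alt_cds_base
      ref_res <- unname(.CODON_TABLE[codon])
      alt_res <- unname(.CODON_TABLE[alt_codon])
      ok <- if (want_nonsyn)
        ref_res != alt_res && ref_res != "*" && alt_res != "*"
      else ref_res == alt_res && ref_res != "*"
      if (!ok) next
      offset <- codon_i * 3L + pic
      gpos <- .cds_offset_to_genomic(tx, offset)
      if (gpos %in% used_pos) next
      ref_g <- substr(genome[[tx$chrom]], gpos + 1L, gpos + 1L)
      alt_g <- if (tx$strand == "+") alt_cds_base
               else .complement_base(alt_cds_base)
      return(data.frame(chrom = tx$chrom, pos = gpos, ref = ref_g,
                        alt = alt_g, transcript_id = tx$id,
                        tag = sprintf("p.%s%d%s", ref_res, codon_i + 1L,
                                      alt_res),
                        category = if (want_nonsyn) "nonsynonymous"
                                   else "synonymous",
                        codon_key = codon_key,
                        stringsAsFactors = FALSE))
    }
    stop("could not place SNV after 500 attempts")
  }
  snvs <- list()
  for (i in seq_len(n_nssnp + n_syn)) {
    used_pos <- vapply(snvs, function(s) s$pos, 0L)
    used_codon <- vapply(snvs, function(s) s$codon_key, "")
    snvs[[i]] <- plant_snv(i <= n_nssnp, used_pos, used_codon)
  }
  snvs <- do.call(rbind, snvs)
  snvs <- snvs[order(snvs$pos), , drop = FALSE]
  vcf_path <- file.path(dir, "sample.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome)[1L],
            nchar(genome[[1L]])),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    sprintf("%s\t%d\t.\t%s\t%s\t99\tPASS\t.",
            snvs$chrom, snvs$pos + 1L, snvs$ref, snvs$alt)
  ), vcf_path)

  ## ---- junctions -----------------------------------------------------
  multi <- names(txs)[vapply(txs, function(t) nrow(t$exons) >= 3L, TRUE)]
  if (length(multi) < n_novel_junctions)
    stop("not enough multi-exon transcripts for the requested junctions")
  skip_tx <- sample(multi, n_novel_junctions)
  novel <- lapply(skip_tx, function(id) {
    tx <- txs[[id]]
    k <- nrow(tx$exons)
    # exons are stored in genomic order; transcription order differs on '-'
    t_order <- if (tx$strand == "+") seq_len(k) else rev(seq_len(k))
    mid <- seq(2L, k - 1L)                      # skipped exon, transcription order
    m <- mid[sample.int(length(mid), 1L)]
    left_t <- t_order[m - 1L]; right_t <- t_order[m + 1L]
    gl <- min(left_t, right_t); gr <- max(left_t, right_t)
    intron_start <- tx$exons[gl, 2L]
    intron_end <- tx$exons[gr, 1L]
    ex_len <- tx$exons[, 2L] - tx$exons[, 1L]
    b1 <- min(bed_flank, ex_len[gl]); b2 <- min(bed_flank, ex_len[gr])
    # expected in-frame peptide: splice-context translation in the frame
    # that continues the upstream CDS (exon boundaries sit on codon
    # boundaries, so the skip preserves frame and introduces no stop)
    left_exon_t <- t_order[m - 1L]; right_exon_t <- t_order[m + 1L]
    exon_seq <- function(i) {
      s <- substr(genome[[tx$chrom]], tx$exons[i, 1L] + 1L, tx$exons[i, 2L])
      if (tx$strand == "-") reverse_complement(s) else s
    }
    LB <- if (tx$strand == "+") b1 else b2
    RB <- if (tx$strand == "+") b2 else b1
    ls <- exon_seq(left_exon_t); rs <- exon_seq(right_exon_t)
    ctx <- paste0(substr(ls, nchar(ls) - LB + 1L, nchar(ls)),
                  substr(rs, 1L, RB))
    up_len <- sum((tx$cds[, 2L] - tx$cds[, 1L])[t_order[seq_len(m - 1L)]])
    P <- up_len - LB
    f <- P %% 3L
    f <- (3L - f) %% 3L
    aa <- translate_nt(ctx, frame = f, truncate_at_stop = TRUE)
    jres <- (LB - f) %/% 3L                     # residues fully left of junction
    data.frame(chrom = tx$chrom, intron_start = intron_start,
               intron_end = intron_end, strand = tx$strand,
               transcript_id = id, skipped_exon = m,
               left_flank = b1, right_flank = b2,
               expected_peptide = aa, span_from = jres, span_to = jres + 1L,
               stringsAsFactors = FALSE)
  })
  novel <- do.call(rbind, novel)

  annotated <- annotation_introns(ann)
  bed_rows <- function(chrom, s, e, strand, b1, b2, name, score) {
    chrom_start <- s - b1
    chrom_end <- e + b2
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t2\t%d,%d\t%d,%d",
            chrom, chrom_start, chrom_end, name, score, strand,
            chrom_start, chrom_end, b1, b2, 0L, e - chrom_start)
  }
  ann_b <- vapply(seq_len(nrow(annotated)), function(i) {
    tx <- txs[[annotated$transcript_id[i]]]
    ex_len <- tx$exons[, 2L] - tx$exons[, 1L]
    gl <- which(tx$exons[, 2L] == annotated$start[i])
    gr <- which(tx$exons[, 1L] == annotated$end[i])
    bed_rows(annotated$chrom[i], annotated$start[i], annotated$end[i],
             annotated$strand[i], min(bed_flank, ex_len[gl]),
             min(bed_flank, ex_len[gr]),
             sprintf("JUNC_ann_%d", i), sample(5:60, 1L))
  }, "")
  nov_b <- vapply(seq_len(nrow(novel)), function(i)
    bed_rows(novel$chrom[i], novel$intron_start[i], novel$intron_end[i],
             novel$strand[i], novel$left_flank[i], novel$right_flank[i],
             sprintf("JUNC_novel_%d", i), sample(5:60, 1L)), "")
  bed_path <- file.path(dir, "junctions.bed")
  writeLines(c(ann_b, nov_b), bed_path)

  ## ---- abundances ----------------------------------------------------
  ids <- names(txs)
  n <- length(ids)
  k <- round(tpm_params$frac_below_1 * n)
  low <- sample(ids, k)
  tpm <- stats::setNames(1 + stats::rlnorm(n, tpm_params$meanlog,
                                           tpm_params$sdlog), ids)
  tpm[low] <- stats::runif(k, 0.01, 0.99)
  hi <- setdiff(ids, low)
  if (length(hi)) tpm[hi[1L]] <- 1.0           # exact-boundary record
  tpm_tab <- data.frame(transcript_id = ids,
                        gene_id = vapply(txs[ids], `[[`, "", "gene_id"),
                        length = vapply(txs[ids], function(t)
                          sum(t$exons[, 2L] - t$exons[, 1L]), 0L),
                        expected_count = round(unname(tpm[ids]) * 10),
                        TPM = unname(tpm[ids]),
                        FPKM = unname(tpm[ids]) * 0.9,
                        stringsAsFactors = FALSE)
  tpm_path <- file.path(dir, "abundance.tsv")
  utils::write.table(tpm_tab, tpm_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(vcf = vcf_path, bed = bed_path, tpm = tpm_path,
       snvs = snvs, novel_junctions = novel, tpm_table = tpm_tab,
       sample = sample, seed = seed)
}

#' Simulate MS/MS spectra from a search database with a truth manifest
#'
#' Samples tryptic peptides from the database's target entries and builds
#' one spectrum per sampled peptide: singly-charged b/y fragment peaks
#' with Gaussian m/z jitter, a stated fraction of fragment peaks dropped,
#' random intensities, and uniform-m/z noise peaks; the precursor m/z is
#' exact at charge 2 or 3. Foreign ("noise") spectra are built the same
#' way from shuffled peptides verified absent from every database entry,
#' giving realistic precursor masses for FDR calibration. The manifest
#' maps every scan to its generating peptide (or `"noise"`).
#'
#' @param db A `search_db` (targets are sampled; decoys ignored).
#' @param n_true Number of spectra from database peptides.
#' @param n_noise Number of foreign-peptide spectra.
#' @param jitter_sd_da Gaussian fragment m/z jitter (Da); must be below
#'   half the product tolerance.
#' @param frac_peaks_dropped Fraction of fragment peaks dropped at random.
#' @param n_noise_peaks Uniform noise peaks added per spectrum.
#' @param seed Integer seed.
#' @param settings A [search_settings()] (length bounds for sampled
#'   peptides).
#' @param stratify Sample peptides by origin (REF / variant-covering SAV /
#'   junction-spanning SJ) so all three classification categories are
#'   exercised; proportions roughly 3:1:1, capped by availability.
#' @param mgf_path Optional path; when given the MGF is written there.
#' @return List with `spectra` (in-memory list), `manifest` (data frame
#'   `scan`, `peptide`, `truth`, `origin`), and `mgf_path` if written.
#' @export
simulate_spectra <- function(db, n_true = 200L, n_noise = 100L,
                             jitter_sd_da = 0.005,
                             frac_peaks_dropped = 0.2,
                             n_noise_peaks = 30L, seed = 1L,
                             settings = search_settings(),
                             stratify = TRUE, mgf_path = NULL) {
  stopifnot(jitter_sd_da < settings$product_tolerance_da / 2)
  set.seed(seed)
  masses <- mass_table()
  targets <- db$entries[db$entries$origin != "DECOY", , drop = FALSE]

  pools <- .peptide_pools(targets, settings)
  pool_all <- unique(c(pools$REF, pools$SAV, pools$SJ))
  if (!length(pool_all)) stop("database yields no eligible peptides")

  picks <- if (stratify) {
    n_sav <- min(length(pools$SAV), ceiling(n_true / 5))
    n_sj <- min(length(pools$SJ), ceiling(n_true / 5))
    n_ref <- n_true - n_sav - n_sj
    ref_pool <- setdiff(pools$REF, c(pools$SAV, pools$SJ))
    c(sample(ref_pool, min(n_ref, length(ref_pool))),
      if (n_sav) sample(pools$SAV, n_sav),
      if (n_sj) sample(pools$SJ, n_sj))
  } else sample(pool_all, min(n_true, length(pool_all)))
  if (length(picks) < n_true)
    picks <- c(picks, sample(pool_all, n_true - length(picks),
                             replace = TRUE))

  # Foreign peptides are tryptic products of *shuffled target proteins*,
  # verified absent from every database sequence. Shuffling at the protein
  # level mirrors the protein-level decoy construction: a peptide-level
  # permutation would keep its source peptide's residue composition and
  # systematically share fragment sums with it, which reversed-protein
  # decoys cannot model.
  all_seqs <- db$entries$sequence
  shuffle_foreign <- function() {
    for (i in 1:200) {
      prot <- targets$sequence[sample.int(nrow(targets), 1L)]
      sh <- paste(sample(strsplit(prot, "", fixed = TRUE)[[1L]]),
                  collapse = "")
      d <- digest_protein(sh, settings)
      d <- d$sequence[nchar(d$sequence) <= 30L]
      d <- d[!vapply(d, function(p) any(grepl(p, all_seqs, fixed = TRUE)),
                     TRUE)]
      if (length(d)) return(d[sample.int(length(d), 1L)])
    }
    stop("could not produce a foreign peptide")
  }
  foreign <- vapply(seq_len(n_noise), function(i) shuffle_foreign(), "")

  make_spectrum <- function(pep, scan, truth_label) {
    z <- sample(2:3, 1L)
    mass <- peptide_monoisotopic_mass(pep, "", settings, masses)
    frag <- theoretical_fragments(pep, "", settings, masses)
    keep <- stats::runif(nrow(frag)) >= frac_peaks_dropped
    if (sum(keep) < 3L) {
      idx <- which(!keep)
      keep[idx[seq_len(3L - sum(keep))]] <- TRUE
    }
    fmz <- frag$mz[keep] + stats::rnorm(sum(keep), 0, jitter_sd_da)
    fint <- stats::runif(sum(keep), 200, 1000)
    if (n_noise_peaks > 0L) {
      nmz <- stats::runif(n_noise_peaks, 100, max(frag$mz) + 200)
      nint <- stats::runif(n_noise_peaks, 10, 150)
      fmz <- c(fmz, nmz); fint <- c(fint, nint)
    }
    o <- order(fmz)
    list(title = scan, scan = scan,
         pepmass = (mass + z * masses$proton) / z,
         charge = z, mz = fmz[o], intensity = fint[o])
  }

  spectra <- vector("list", length(picks) + length(foreign))
  manifest <- vector("list", length(spectra))
  # mirror the classifier's precedence (reference first, then SAV, then SJ)
  origin_of <- function(p) {
    if (p %in% pools$SAV) "SAV" else if (p %in% pools$SJ) "SJ" else "REF"
  }
  for (i in seq_along(picks)) {
    scan <- sprintf("scan_%04d", i)
    spectra[[i]] <- make_spectrum(picks[i], scan, picks[i])
    manifest[[i]] <- data.frame(scan = scan, peptide = picks[i],
                                truth = "true", origin = origin_of(picks[i]),
                                stringsAsFactors = FALSE)
  }
  for (j in seq_along(foreign)) {
    i <- length(picks) + j
    scan <- sprintf("scan_%04d", i)
    spectra[[i]] <- make_spectrum(foreign[j], scan, "noise")
    manifest[[i]] <- data.frame(scan = scan, peptide = foreign[j],
                                truth = "noise", origin = "noise",
                                stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  out <- list(spectra = spectra, manifest = manifest)
  if (!is.null(mgf_path)) {
    write_mgf(spectra, mgf_path)
    jsonlite::write_json(manifest, sub("\\.mgf$", "_manifest.json", mgf_path),
                         dataframe = "rows", auto_unbox = TRUE)
    out$mgf_path <- mgf_path
  }
  out
}

# eligible tryptic peptides per origin; SAV peptides must cover the
# substituted residue and SJ peptides the junction pair, and neither may
# occur in any REF entry
.peptide_pools <- function(targets, settings) {
  digs <- lapply(seq_len(nrow(targets)), function(i) {
    d <- digest_protein(targets$sequence[i], settings)
    d <- d[nchar(d$sequence) <= 30L, , drop = FALSE]   # spectra-friendly
    if (!nrow(d)) return(NULL)
    d$origin <- targets$origin[i]
    d$entry <- i
    d
  })
  digs <- do.call(rbind, digs)
  ref_seqs <- targets$sequence[targets$origin == "REF"]
  in_ref <- function(p) any(grepl(p, ref_seqs, fixed = TRUE))
  pool <- list(REF = character(), SAV = character(), SJ = character())
  if (is.null(digs)) return(pool)
  pool$REF <- unique(digs$sequence[digs$origin == "REF"])
  sav_rows <- digs[digs$origin == "SAV", , drop = FALSE]
  if (nrow(sav_rows)) {
    tags <- parse_sav_tag(targets$provenance[sav_rows$entry])
    cover <- sav_rows$start <= tags$position &
      tags$position <= sav_rows$start + nchar(sav_rows$sequence) - 1L
    cand <- unique(sav_rows$sequence[cover])
    pool$SAV <- cand[!vapply(cand, in_ref, TRUE)]
  }
  sj_rows <- digs[digs$origin == "SJ", , drop = FALSE]
  if (nrow(sj_rows)) {
    tags <- parse_sj_tag(targets$provenance[sj_rows$entry])
    cover <- sj_rows$start <= tags$span_from &
      tags$span_to <= sj_rows$start + nchar(sj_rows$sequence) - 1L
    cand <- unique(sj_rows$sequence[cover])
    pool$SJ <- cand[!vapply(cand, in_ref, TRUE)]
  }
  pool
}
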