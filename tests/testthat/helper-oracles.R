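# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# Translation oracle: Biostrings' genetic code, with the package's
# contract that any codon containing a non-ACGT base yields 'X'.
oracle_translate <- function(nt, frame = 0, truncate_at_stop = FALSE) {
  n <- nchar(nt)
  if (n - frame < 3) return("")
  starts <- seq(frame + 1, n - 2, by = 3)
  codons <- substring(nt, starts, starts + 2)
  aa <- ifelse(grepl("^[ACGT]{3}$", codons),
               Biostrings::GENETIC_CODE[codons], "X")
  aa[is.na(aa)] <- "X"
  if (truncate_at_stop) {
    s <- which(aa == "*")
    if (length(s)) aa <- aa[seq_len(s[1] - 1)]
  }
  paste(aa, collapse = "")
}

oracle_revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# Mass oracle: residue masses recomputed from elemental composition and
# monoisotopic element masses (a different route from the residue table).
oracle_residue_mass <- local({
  el <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
          O = 15.9949146221, S = 31.97207069)
  comp <- list(
    G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1))
  vapply(comp, function(f) sum(el[names(f)] * f), 0)
})
ORACLE_WATER <- 2 * 1.0078250319 + 15.9949146221
ORACLE_PROTON <- 1.00727646
ORACLE_CAM <- sum(c(C = 12, H = 1.0078250319, N = 14.0030740052,
                    O = 15.9949146221)[c("C", "C", "H", "H", "H", "N", "O")])
ORACLE_OX <- 15.9949146221

oracle_peptide_mass <- function(seq, ox_sites = integer()) {
  res <- strsplit(seq, "")[[1]]
  m <- sum(oracle_residue_mass[res]) + ORACLE_WATER
  m <- m + sum(res == "C") * ORACLE_CAM
  m + length(ox_sites) * ORACLE_OX
}

oracle_fragments <- function(seq, ox_sites = integer()) {
  res <- strsplit(seq, "")[[1]]
  rm <- oracle_residue_mass[res]
  rm[res == "C"] <- rm[res == "C"] + ORACLE_CAM
  rm[ox_sites] <- rm[ox_sites] + ORACLE_OX
  n <- length(res)
  list(b = vapply(1:(n - 1), function(i) sum(rm[1:i]) + ORACLE_PROTON, 0),
       y = vapply(1:(n - 1), function(i)
         sum(rm[(n - i + 1):n]) + ORACLE_WATER + ORACLE_PROTON, 0))
}

# Digestion oracle: enumerate every contiguous run of inter-cleavage
# segments with at most max_mc internal cleavage sites skipped.
oracle_digest <- function(protein, max_mc = 2, min_len = 1, max_len = Inf) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  cuts <- which(res %in% c("K", "R"))
  bounds <- unique(c(0, cuts, n))
  peps <- character()
  for (i in seq_along(bounds)[-length(bounds)]) {
    for (j in (i + 1):min(length(bounds), i + 1 + max_mc)) {
      p <- substr(protein, bounds[i] + 1, bounds[j])
      peps <- c(peps, p)
      if (bounds[i] == 0 && startsWith(p, "M") && nchar(p) > 1)
        peps <- c(peps, substr(p, 2, nchar(p)))
    }
  }
  peps <- peps[nchar(peps) >= min_len & nchar(peps) <= max_len &
                 !grepl("[^ACDEFGHIKLMNPQRSTVWY]", peps)]
  sort(unique(peps))
}

random_protein <- function(n) {
  paste(sample(names(oracle_residue_mass), n, replace = TRUE),
        collapse = "")
}

random_nt <- function(n, with_n = FALSE) {
  alph <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(alph, n, replace = TRUE), collapse = "")
}

# A hand-built two-exon plus/minus annotation used by the SAV tests.
# CDS is "ATGAAACCC..." split across exons with a short intron.
tiny_annotation <- function(strand = "+") {
  cds_nt <- "ATGAAACCCGGGTTTAGA"         # M K P G F R
  if (strand == "+") {
    chrom <- paste0("ACGT", substr(cds_nt, 1, 9), "GTAAAG",
                    substr(cds_nt, 10, 18), "TTTT")
    exons <- rbind(c(4L, 13L), c(19L, 28L))
  } else {
    left <- sspsearch::reverse_complement(substr(cds_nt, 10, 18))
    right <- sspsearch::reverse_complement(substr(cds_nt, 1, 9))
    chrom <- paste0("ACGT", left, "GTAAAG", right, "TTTT")
    exons <- rbind(c(4L, 13L), c(19L, 28L))
  }
  tx <- list(id = "TX1", gene_id = "G1", chrom = "c1", strand = strand,
             exons = exons, cds = exons, frame = 0L, complete = TRUE)
  genome_annotation(c(c1 = chrom),
                    list(list(id = "G1", strand = strand,
                              transcripts = list(TX1 = tx))))
}
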