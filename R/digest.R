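#' In-silico tryptic digestion of a protein
#'
#' Cleaves C-terminal to every K and R -- including before proline (the
#' "no proline rule") -- and emits every product with up to
#' `max_missed_cleavages` missed cleavages. With variable initiator
#' methionine, protein-N-terminal peptides starting with M are emitted
#' both with and without the initiator Met. Products outside the length
#' bounds, or containing a non-standard residue (`X`), are dropped.
#'
#' @param protein A protein sequence string, or a one-row
#'   `protein_entries` slice (its `sequence` is used).
#' @param settings A [search_settings()] object.
#' @return Data frame with `sequence`, `start` (1-based position in the
#'   protein), `n_missed` and `nterm_met_removed`.
#' @examples
#' s <- search_settings(min_peptide_length = 1L)
#' digest_protein("MKRPASKR", s)$sequence
#' @export
digest_protein <- function(protein, settings = search_settings()) {
  if (is.data.frame(protein)) protein <- protein$sequence
  stopifnot(is.character(protein), length(protein) == 1L)
  n <- nchar(protein)
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  cuts <- which(res %in% c("K", "R"))
  bounds <- unique(c(0L, cuts, n))          # segment boundaries
  nb <- length(bounds)
  out_seq <- character(); out_start <- integer()
  out_missed <- integer(); out_trim <- logical()
  max_mc <- settings$max_missed_cleavages
  for (i in seq_len(nb - 1L)) {
    for (j in seq.int(i + 1L, min(nb, i + 1L + max_mc))) {
      pep <- substr(protein, bounds[i] + 1L, bounds[j])
      out_seq <- c(out_seq, pep)
      out_start <- c(out_start, bounds[i] + 1L)
      out_missed <- c(out_missed, j - i - 1L)
      out_trim <- c(out_trim, FALSE)
      if (settings$initiator_methionine == "variable" &&
          bounds[i] == 0L && startsWith(pep, "M") && nchar(pep) > 1L) {
        out_seq <- c(out_seq, substr(pep, 2L, nchar(pep)))
        out_start <- c(out_start, 2L)
        out_missed <- c(out_missed, j - i - 1L)
        out_trim <- c(out_trim, TRUE)
      }
    }
  }
  keep <- nchar(out_seq) >= settings$min_peptide_length &
    nchar(out_seq) <= settings$max_peptide_length &
    grepl(.AA_REGEX, out_seq)
  data.frame(sequence = out_seq[keep], start = out_start[keep],
             n_missed = out_missed[keep],
             nterm_met_removed = out_trim[keep],
             stringsAsFactors = FALSE)
}

#' Enumerate variable-modification isoforms of a peptide
#'
#' Carbamidomethylation of cysteine is fixed (applied unconditionally to
#' every C at mass-computation time); oxidation of methionine is variable,
#' yielding one isoform per subset of M positions. Subsets are enumerated
#' in deterministic binary-counting order over the ascending site list; if
#' the number of subsets exceeds the isoform cap, the first
#' `max_mod_isoforms` are emitted and the truncation is flagged in the
#' `"truncated"` attribute.
#'
#' @param sequence Peptide sequence.
#' @param settings A [search_settings()] object.
#' @return Data frame with `sequence` and `ox_sites` (comma-separated
#'   1-based M positions oxidized; `""` for the unmodified isoform).
#' @export
enumerate_mod_isoforms <- function(sequence, settings = search_settings()) {
  sites <- which(strsplit(sequence, "", fixed = TRUE)[[1L]] == "M")
  m <- length(sites)
  n_iso <- 2^m
  truncated <- n_iso > settings$max_mod_isoforms
  n_emit <- min(n_iso, settings$max_mod_isoforms)
  ox <- vapply(seq_len(n_emit) - 1L, function(mask) {
    chosen <- sites[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L]
    paste(chosen, collapse = ",")
  }, "")
  out <- data.frame(sequence = sequence, ox_sites = ox,
                    stringsAsFactors = FALSE)
  attr(out, "truncated") <- truncated
  if (truncated)
    message("modification isoforms capped at ", settings$max_mod_isoforms,
            " for peptide ", sequence)
  out
}

.parse_ox <- function(ox_sites) {
  if (is.na(ox_sites) || !nzchar(ox_sites)) return(integer())
  as.integer(strsplit(ox_sites, ",", fixed = TRUE)[[1L]])
}

# per-residue masses of a peptide with fixed CAM-C and the given oxidized sites
.residue_masses <- function(sequence, ox_sites = "", settings, masses) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  rm <- masses$residues[res]
  if (anyNA(rm))
    stop("residue(s) without mass in peptide ", sequence)
  rm <- unname(rm)
  rm[res == "C"] <- rm[res == "C"] + settings$fixed_cys_mod
  ox <- .parse_ox(ox_sites)
  if (length(ox)) {
    if (any(res[ox] != "M")) stop("oxidation site is not M in ", sequence)
    rm[ox] <- rm[ox] + settings$variable_met_mod
  }
  rm
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus water plus modification deltas
#' (carbamidomethyl-C fixed, oxidation at the listed M sites).
#'
#' @param sequence Peptide sequence.
#' @param ox_sites Comma-separated oxidized M positions (`""` for none).
#' @param settings A [search_settings()] object.
#' @param masses A [mass_table()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_monoisotopic_mass("PEPTIDE")  # 799.36 Da
#' @export
peptide_monoisotopic_mass <- function(sequence, ox_sites = "",
                                      settings = search_settings(),
                                      masses = mass_table()) {
  sum(.residue_masses(sequence, ox_sites, settings, masses)) + masses$water
}

#' Theoretical singly-charged b and y fragment ions
#'
#' b-ions are prefix residue sums plus a proton; y-ions are suffix sums
#' plus water plus a proton, for indices 1..n-1. Site modifications are
#' carried by the covering prefix or suffix. For every index `i`,
#' `b_i + y_(n-i) = M + water + 2*proton`.
#'
#' @inheritParams peptide_monoisotopic_mass
#' @return Data frame with `type` (`"b"`/`"y"`), `index` and `mz`, sorted
#'   by `mz`.
#' @export
theoretical_fragments <- function(sequence, ox_sites = "",
                                  settings = search_settings(),
                                  masses = mass_table()) {
  n <- nchar(sequence)
  if (n < 2L) stop("peptide must have at least 2 residues")
  rm <- .residue_masses(sequence, ox_sites, settings, masses)
  pre <- cumsum(rm)
  b <- pre[-n] + masses$proton
  y <- (pre[n] - pre[-n]) + masses$water + masses$proton
  out <- data.frame(
    type = c(rep("b", n - 1L), rep("y", n - 1L)),
    index = c(seq_len(n - 1L), seq_len(n - 1L)),
    mz = c(b, rev(y)),
    stringsAsFactors = FALSE)
  out[order(out$mz, out$type, out$index), , drop = FALSE]
}
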