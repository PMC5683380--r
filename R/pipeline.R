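#' Build a sample-specific search database (SSdb)
#'
#' Runs the three database workflows and concatenates their records:
#' reference entries reduced to transcripts at or above the TPM
#' threshold, SAV entries from nonsynonymous variant calls, and SJ
#' entries from junctions absent from the gene model.
#'
#' @param annotation A `genome_annotation` with chromosome sequences.
#' @param variants Variant calls (see [read_vcf_calls()]), or `NULL`.
#' @param junctions Junction table (see [read_junction_bed()]), or `NULL`.
#' @param abundances TPM table (see [read_tpm_table()]), or `NULL` to
#'   skip reduction.
#' @param settings A [search_settings()] (minimum peptide length bounds
#'   SAV truncations and SJ segments).
#' @param name Database name.
#' @param tpm_threshold Minimum TPM retained.
#' @param flank_nt Junction flank length (nt per side).
#' @return A `search_db` (without decoys; see [add_decoys()]).
#' @export
build_ssdb <- function(annotation, variants = NULL, junctions = NULL,
                       abundances = NULL, settings = search_settings(),
                       name = "SSdb", tpm_threshold = 1.0, flank_nt = 66L) {
  ref <- reference_entries(annotation)
  reduced <- if (!is.null(abundances))
    reduce_by_tpm(ref, abundances, tpm_threshold) else ref
  sav <- NULL
  if (!is.null(variants) && nrow(variants)) {
    effects <- classify_variant_effects(annotation, variants)
    sav <- build_sav_entries(effects, ref,
                             min_length = settings$min_peptide_length)
  }
  sj <- NULL
  if (!is.null(junctions) && nrow(junctions)) {
    novel <- detect_novel_junctions(junctions, annotation)
    sj <- junction_db(novel, annotation$chromosomes, flank_nt = flank_nt,
                      min_length = settings$min_peptide_length)
  }
  assemble_database(reduced, sav, sj, name = name)
}

#' Build the reference database (REFdb)
#'
#' The degenerate assembly: every reference protein, no SAV or SJ
#' records, no abundance reduction.
#'
#' @param annotation A `genome_annotation` with chromosome sequences.
#' @param name Database name.
#' @return A `search_db` (without decoys).
#' @export
build_refdb <- function(annotation, name = "REFdb") {
  assemble_database(reference_entries(annotation), NULL, NULL, name = name)
}
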