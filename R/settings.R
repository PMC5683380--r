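#' Search engine settings
#'
#' The complete parameter block of the Morpheus-style search: tryptic
#' digestion with no proline rule, up to 2 missed cleavages, variable
#' initiator methionine, fixed carbamidomethyl-C and variable oxidation-M,
#' wide monoisotopic precursor window (+/- 2.1 Da, no monoisotopic-peak
#' correction) with a tight product tolerance (+/- 0.025 Da), and a 1%
#' target-decoy FDR cap.
#'
#' @param precursor_charge_min,precursor_charge_max Assumed precursor charge
#'   states evaluated when a spectrum carries no charge annotation.
#' @param max_peaks MS/MS peak filtering: number of most-intense peaks kept.
#' @param assign_charge_states Logical; product peaks are treated as singly
#'   charged (charge deconvolution is not performed).
#' @param max_missed_cleavages Maximum tryptic missed cleavages.
#' @param initiator_methionine `"variable"`: protein-N-terminal peptides are
#'   generated both with and without the initiator Met.
#' @param fixed_cys_mod Fixed cysteine mass delta in Da (carbamidomethyl).
#' @param variable_met_mod Variable methionine mass delta in Da (oxidation).
#' @param max_mod_isoforms Cap on variable-modification isoforms per peptide.
#' @param precursor_tolerance_da Precursor mass tolerance, +/- Da, monoisotopic.
#' @param product_tolerance_da Product m/z tolerance, +/- Da, monoisotopic.
#' @param max_fdr Maximum false discovery rate for accepted PSMs (q-value cap).
#' @param min_peptide_length,max_peptide_length Digestion length bounds in
#'   residues.
#' @return A list of class `search_settings`.
#' @examples
#' s <- search_settings()
#' s$precursor_tolerance_da  # 2.1
#' @export
search_settings <- function(precursor_charge_min = 2L,
                            precursor_charge_max = 4L,
                            max_peaks = 400L,
                            assign_charge_states = TRUE,
                            max_missed_cleavages = 2L,
                            initiator_methionine = "variable",
                            fixed_cys_mod = 57.02146,
                            variable_met_mod = 15.99491,
                            max_mod_isoforms = 1024L,
                            precursor_tolerance_da = 2.1,
                            product_tolerance_da = 0.025,
                            max_fdr = 0.01,
                            min_peptide_length = 6L,
                            max_peptide_length = 50L) {
  stopifnot(precursor_charge_min >= 1L,
            precursor_charge_min <= precursor_charge_max,
            precursor_tolerance_da > 0, product_tolerance_da > 0,
            max_fdr > 0, max_fdr <= 1,
            min_peptide_length >= 1L,
            min_peptide_length <= max_peptide_length)
  initiator_methionine <- match.arg(initiator_methionine,
                                    c("variable", "retain", "cleave"))
  structure(list(
    precursor_charge_min = as.integer(precursor_charge_min),
    precursor_charge_max = as.integer(precursor_charge_max),
    max_peaks = as.integer(max_peaks),
    assign_charge_states = isTRUE(assign_charge_states),
    protease = "trypsin-no-proline-rule",
    max_missed_cleavages = as.integer(max_missed_cleavages),
    initiator_methionine = initiator_methionine,
    fixed_cys_mod = fixed_cys_mod,
    variable_met_mod = variable_met_mod,
    max_mod_isoforms = as.integer(max_mod_isoforms),
    precursor_tolerance_da = precursor_tolerance_da,
    monoisotopic_correction = FALSE,
    product_tolerance_da = product_tolerance_da,
    max_fdr = max_fdr,
    min_peptide_length = as.integer(min_peptide_length),
    max_peptide_length = as.integer(max_peptide_length)
  ), class = "search_settings")
}

#' @export
print.search_settings <- function(x, ...) {
  cat("Search settings (Morpheus-style)\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Monoisotopic mass table
#'
#' Monoisotopic residue masses of the 20 standard amino acids together with
#' the mass of water (added once per peptide) and the proton mass (added per
#' charge). Values follow standard IUPAC/Unimod monoisotopic tables.
#'
#' @return A list with `residues` (named numeric vector), `water` and
#'   `proton` (Da).
#' @examples
#' mass_table()$residues[["G"]]  # 57.02146
#' @export
mass_table <- function() {
  list(
    residues = c(
      G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
      V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
      I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
      K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
      F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    water = 18.010565,
    proton = 1.007276
  )
}
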