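#' Build a mass-indexed candidate peptide table from a database
#'
#' Digests every entry (targets and decoys), collapses identical peptide
#' sequences across proteins (a candidate is a decoy only if *all* its
#' parent proteins are decoys), enumerates modification isoforms, computes
#' monoisotopic masses and sorts by mass so the precursor window can be
#' located by binary search.
#'
#' @param db A `search_db` (normally with decoys appended).
#' @param settings A [search_settings()] object.
#' @return A `candidate_index`: list with `table` (data frame `sequence`,
#'   `ox_sites`, `mass`, `accessions`, `is_decoy`, sorted by mass) and the
#'   settings used.
#' @export
build_candidate_index <- function(db, settings = search_settings()) {
  stopifnot(inherits(db, "search_db"))
  masses <- mass_table()
  digests <- lapply(seq_len(nrow(db$entries)), function(i) {
    d <- digest_protein(db$entries$sequence[i], settings)
    if (nrow(d) == 0L) return(NULL)
    data.frame(sequence = unique(d$sequence),
               accession = db$entries$accession[i],
               is_decoy_parent = db$entries$origin[i] == "DECOY",
               stringsAsFactors = FALSE)
  })
  digests <- do.call(rbind, digests)
  if (is.null(digests) || nrow(digests) == 0L)
    stop("database yields no peptide candidates under these settings")
  acc_by_pep <- split(digests$accession, digests$sequence)
  decoy_by_pep <- vapply(split(digests$is_decoy_parent, digests$sequence),
                         all, TRUE)
  peptides <- names(acc_by_pep)

  iso <- lapply(peptides, function(p) enumerate_mod_isoforms(p, settings))
  iso <- do.call(rbind, iso)
  iso$mass <- vapply(seq_len(nrow(iso)), function(i)
    peptide_monoisotopic_mass(iso$sequence[i], iso$ox_sites[i],
                              settings, masses), 0)
  iso$accessions <- vapply(acc_by_pep[iso$sequence], function(a)
    paste(sort(unique(a)), collapse = ";"), "")
  iso$is_decoy <- unname(decoy_by_pep[iso$sequence])
  iso <- iso[order(iso$mass, iso$sequence, iso$ox_sites), , drop = FALSE]
  rownames(iso) <- NULL
  structure(list(table = iso, settings = settings),
            class = "candidate_index")
}

#' Score a peptide candidate against a spectrum
#'
#' The Morpheus score: the number of theoretical b/y fragments with at
#' least one observed peak within the product tolerance, plus the summed
#' intensity of the matched peaks as a fraction of the spectrum's total
#' ion current. Each observed peak is creditable to at most one
#' theoretical fragment (its nearest in m/z; equidistant ties go to the
#' lower-m/z fragment).
#'
#' @param spectrum A (preprocessed) spectrum list.
#' @param sequence Peptide sequence.
#' @param ox_sites Comma-separated oxidized M sites (`""` for none).
#' @param settings A [search_settings()] object.
#' @param masses A [mass_table()].
#' @return The score (matched-fragment count + matched-intensity fraction).
#' @export
score_psm <- function(spectrum, sequence, ox_sites = "",
                      settings = search_settings(), masses = mass_table()) {
  if (length(spectrum$mz) == 0L) stop("empty spectrum")
  frag <- theoretical_fragments(sequence, ox_sites, settings, masses)
  fmz <- frag$mz
  tol <- settings$product_tolerance_da
  pmz <- spectrum$mz
  # nearest fragment for each peak (fmz sorted ascending)
  idx <- findInterval(pmz, fmz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(fmz))
  d_lo <- abs(pmz - fmz[lo])
  d_hi <- abs(pmz - fmz[hi])
  nearest <- ifelse(d_hi < d_lo, hi, lo)   # ties -> lower-m/z fragment
  dist <- pmin(d_lo, d_hi)
  credited <- dist <= tol
  if (!any(credited)) return(0)
  matched_frags <- unique(nearest[credited])
  frac <- sum(spectrum$intensity[credited]) / sum(spectrum$intensity)
  length(matched_frags) + frac
}

#' Search spectra against a database
#'
#' For each spectrum the neutral precursor mass is computed as
#' `z * m/z - z * proton` -- using the annotated charge when present,
#' otherwise every assumed charge state in the settings range -- and all
#' candidates within the precursor tolerance are scored. No
#' monoisotopic-peak (isotope offset) correction is applied. The
#' best-scoring PSM per spectrum is retained; score ties prefer targets
#' over decoys, then the lexicographically smallest peptide.
#'
#' @param db A `search_db` with decoys, or a prebuilt `candidate_index`.
#' @param spectra List of spectra (see [read_mgf()]).
#' @param settings A [search_settings()] object.
#' @return Data frame of PSMs (`scan`, `peptide`, `ox_sites`, `charge`,
#'   `precursor_neutral`, `mass`, `score`, `is_decoy`, `accessions`,
#'   `q = NA`); spectra with no in-window candidate contribute no row and
#'   are counted in the `"n_unmatched"` attribute.
#' @export
run_search <- function(db, spectra, settings = search_settings()) {
  index <- if (inherits(db, "candidate_index")) db
           else build_candidate_index(db, settings)
  tab <- index$table
  masses <- mass_table()
  tol <- settings$precursor_tolerance_da
  rows <- vector("list", length(spectra))
  n_unmatched <- 0L
  for (k in seq_along(spectra)) {
    sp <- preprocess_spectrum(spectra[[k]], settings)
    zs <- if (!is.null(sp$charge) && !is.na(sp$charge)) sp$charge
          else seq.int(settings$precursor_charge_min,
                       settings$precursor_charge_max)
    best <- NULL
    for (z in zs) {
      neutral <- z * sp$pepmass - z * masses$proton
      i0 <- findInterval(neutral - tol, tab$mass) + 1L
      i1 <- findInterval(neutral + tol, tab$mass)
      if (i1 < i0) next
      for (i in seq.int(i0, i1)) {
        sc <- score_psm(sp, tab$sequence[i], tab$ox_sites[i], settings, masses)
        cand <- list(score = sc, i = i, z = z, neutral = neutral)
        if (is.null(best)) { best <- cand; next }
        better <- sc > best$score ||
          (sc == best$score && tab$is_decoy[best$i] && !tab$is_decoy[i]) ||
          (sc == best$score && tab$is_decoy[best$i] == tab$is_decoy[i] &&
             tab$sequence[i] < tab$sequence[best$i])
        if (better) best <- cand
      }
    }
    if (is.null(best)) { n_unmatched <- n_unmatched + 1L; next }
    i <- best$i
    rows[[k]] <- data.frame(
      scan = spectra[[k]]$scan, peptide = tab$sequence[i],
      ox_sites = tab$ox_sites[i], charge = best$z,
      precursor_neutral = best$neutral, mass = tab$mass[i],
      score = best$score, is_decoy = tab$is_decoy[i],
      accessions = tab$accessions[i], q = NA_real_,
      stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, rows)
  if (is.null(psms))
    psms <- data.frame(scan = character(), peptide = character(),
                       ox_sites = character(), charge = integer(),
                       precursor_neutral = numeric(), mass = numeric(),
                       score = numeric(), is_decoy = logical(),
                       accessions = character(), q = numeric(),
                       stringsAsFactors = FALSE)
  rownames(psms) <- NULL
  attr(psms, "n_unmatched") <- n_unmatched
  psms
}

#' Compute target-decoy q-values
#'
#' PSMs are ranked by score; at each score threshold (ties counted
#' together) the FDR estimate is `decoys at or above / targets at or
#' above` (0 when no targets). The q-value of a PSM is the minimum FDR
#' over all thresholds at or below its score (monotonized), capped at 1.
#' The accepted set at the settings' FDR cap is flagged in `accepted`.
#'
#' @param psms PSM data frame from [run_search()] (one best PSM per
#'   spectrum).
#' @param settings A [search_settings()] object.
#' @return The PSMs with `q` filled and an `accepted` logical column
#'   (targets with `q <= max_fdr`).
#' @export
compute_q_values <- function(psms, settings = search_settings()) {
  if (nrow(psms) == 0L) {
    psms$accepted <- logical()
    return(psms)
  }
  o <- order(-psms$score)
  s <- psms$score[o]
  dec <- psms$is_decoy[o]
  cum_d <- cumsum(dec)
  cum_t <- cumsum(!dec)
  # group ties: FDR evaluated at the last PSM of each distinct score
  last_of_score <- !duplicated(s, fromLast = TRUE)
  fdr <- ifelse(cum_t == 0, 0, cum_d / cum_t)
  # propagate each score group's full-group FDR to all its members
  grp_fdr <- fdr
  grp_fdr[!last_of_score] <- NA
  grp_fdr <- rev(cummin_na(rev(grp_fdr)))
  # monotonize: q = min FDR at this or any lower threshold
  q <- rev(cummin(rev(pmin(grp_fdr, 1))))
  psms$q[o] <- q
  psms$accepted <- !psms$is_decoy & psms$q <= settings$max_fdr
  psms
}

# carry the next non-NA value backwards (used to spread tie-group FDRs)
cummin_na <- function(x) {
  last <- Inf
  for (i in seq_along(x)) {
    if (!is.na(x[i])) last <- x[i]
    x[i] <- last
  }
  x
}

#' Parsimony protein grouping
#'
#' Maps accepted peptides to all target proteins containing them, merges
#' proteins with identical peptide sets into one group, and greedily
#' discards groups whose peptide set is a proper subset of another's.
#' Output order is deterministic (by first accession).
#'
#' @param accepted_psms Accepted PSM rows (targets at the FDR cap).
#' @param db Optional `search_db`; when supplied, peptides are re-mapped
#'   against every target entry (catching shared peptides the index
#'   already collapsed). Otherwise the PSM `accessions` column is used.
#' @return Data frame with `accessions` (`;`-joined group members) and
#'   `peptides` (`;`-joined supporting peptide set).
#' @export
group_proteins <- function(accepted_psms, db = NULL) {
  peps <- unique(accepted_psms$peptide)
  if (!length(peps))
    return(data.frame(accessions = character(), peptides = character(),
                      stringsAsFactors = FALSE))
  if (!is.null(db)) {
    targets <- db$entries[db$entries$origin != "DECOY", , drop = FALSE]
    prot_peps <- lapply(seq_len(nrow(targets)), function(i) {
      hit <- vapply(peps, function(p)
        grepl(p, targets$sequence[i], fixed = TRUE), TRUE)
      peps[hit]
    })
    names(prot_peps) <- targets$accession
  } else {
    pairs <- do.call(rbind, lapply(seq_len(nrow(accepted_psms)), function(i) {
      acc <- strsplit(accepted_psms$accessions[i], ";", fixed = TRUE)[[1L]]
      acc <- acc[!startsWith(acc, "DECOY_")]
      data.frame(accession = acc, peptide = accepted_psms$peptide[i],
                 stringsAsFactors = FALSE)
    }))
    prot_peps <- lapply(split(pairs$peptide, pairs$accession), unique)
  }
  prot_peps <- prot_peps[lengths(prot_peps) > 0L]
  if (!length(prot_peps))
    return(data.frame(accessions = character(), peptides = character(),
                      stringsAsFactors = FALSE))
  prot_peps <- lapply(prot_peps, sort)
  sig <- vapply(prot_peps, paste, "", collapse = ";")
  groups <- lapply(split(names(sig), sig), sort)
  group_peps <- strsplit(names(groups), ";", fixed = TRUE)
  # greedy parsimony: drop groups whose peptide set is a subset of another
  keep <- rep(TRUE, length(groups))
  sizes <- lengths(group_peps)
  for (a in order(sizes)) {
    for (b in order(-sizes)) {
      if (a == b || !keep[b]) next
      if (sizes[a] < sizes[b] && all(group_peps[[a]] %in% group_peps[[b]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  out <- data.frame(
    accessions = vapply(groups[keep], paste, "", collapse = ";"),
    peptides = names(groups)[keep],
    stringsAsFactors = FALSE)
  out <- out[order(out$accessions), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a PSM table
#'
#' TSV with one row per PSM, modeled on a Morpheus `.PSMs.tsv`.
#'
#' @param psms PSM data frame.
#' @param path File path.
#' @return `path` (write) or the PSM data frame (read).
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
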