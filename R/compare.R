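#' Label a PSM table with its source
#'
#' @param psms PSM data frame.
#' @param sample,fraction,database Source labels (database is typically
#'   `"SSdb"` or `"REFdb"`).
#' @return The PSM table with `sample`, `fraction`, `database` columns.
#' @export
label_psms <- function(psms, sample, fraction, database) {
  psms$sample <- sample
  psms$fraction <- fraction
  psms$database <- database
  psms
}

#' Merge labelled PSM tables
#'
#' Row-binds per-fraction, per-database PSM tables (typically 3 fractions
#' x 2 databases = 6 per sample) into one table keyed by
#' (sample, fraction, scan, database). Duplicate keys across inputs are a
#' hard error.
#'
#' @param psm_tables List of labelled PSM tables (see [label_psms()]).
#' @return The merged PSM table.
#' @export
merge_psm_tables <- function(psm_tables) {
  psm_tables <- psm_tables[vapply(psm_tables, nrow, 0L) > 0L]
  if (!length(psm_tables))
    stop("no PSM rows to merge")
  need <- c("sample", "fraction", "database", "scan")
  for (t in psm_tables)
    if (!all(need %in% names(t)))
      stop("PSM tables must carry sample, fraction and database labels")
  merged <- do.call(rbind, psm_tables)
  key <- paste(merged$sample, merged$fraction, merged$scan, merged$database,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (sample, fraction, scan, database) key(s), e.g. ",
         gsub("\r", ":", key[dup][1L]))
  rownames(merged) <- NULL
  merged
}

#' Accepted-peptide rollup per (sample, database)
#'
#' Distinct accepted peptide sequences per sample and database.
#' Modifications are stripped for identity (the peptide string itself is
#' unmodified; oxidation states live in `ox_sites`); I and L remain
#' distinct.
#'
#' @param merged Merged PSM table with an `accepted` column (see
#'   [compute_q_values()]).
#' @return Named list `sets[[sample]][[database]]` of peptide character
#'   vectors.
#' @export
peptide_rollup <- function(merged) {
  acc <- merged[merged$accepted, , drop = FALSE]
  lapply(split(acc, acc$sample), function(s)
    lapply(split(s$peptide, s$database), function(p) sort(unique(p))))
}

#' Classify peptides unique to the sample-specific database
#'
#' Partitions `ssdb_peptides \\ refdb_peptides` into the three categories,
#' evaluated in order: (a) *reference-recovered* -- the peptide is a
#' substring of some reference protein (identifiable in principle by the
#' reference database, recovered only under the smaller SSdb);
#' (b) *SAV* -- the peptide maps to an SAV entry and covers the
#' substituted residue; (c) *novel-SJ* -- the peptide maps to an SJ entry
#' and spans the junction residue pair. A peptide matching none of these
#' indicates index corruption and is a hard error. The precedence makes
#' novelty calling conservative: anything explainable by the reference is
#' never called novel.
#'
#' @param ssdb_peptides,refdb_peptides Accepted peptide sets (q at or
#'   below the FDR cap) for the two searches.
#' @param ssdb The sample-specific `search_db` (targets are inspected).
#' @param reference_proteome `protein_entries` of the full reference
#'   proteome.
#' @return A `comparison_result`: list with `ssdb_only` (data frame
#'   `peptide`, `category`), `refdb_only`, `shared` and `counts`.
#' @export
classify_unique_peptides <- function(ssdb_peptides, refdb_peptides,
                                     ssdb, reference_proteome) {
  ssdb_peptides <- unique(ssdb_peptides)
  refdb_peptides <- unique(refdb_peptides)
  ssdb_only <- setdiff(ssdb_peptides, refdb_peptides)
  shared <- intersect(ssdb_peptides, refdb_peptides)
  refdb_only <- setdiff(refdb_peptides, ssdb_peptides)

  entries <- ssdb$entries[ssdb$entries$origin != "DECOY", , drop = FALSE]
  sav <- entries[entries$origin == "SAV", , drop = FALSE]
  sj <- entries[entries$origin == "SJ", , drop = FALSE]
  sav_tags <- if (nrow(sav)) parse_sav_tag(sav$provenance) else NULL
  sj_tags <- if (nrow(sj)) parse_sj_tag(sj$provenance) else NULL

  covers <- function(peptide, entry_seq, from, to) {
    # does any occurrence of peptide in entry_seq cover residues from..to?
    hits <- gregexpr(peptide, entry_seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(FALSE)
    any(hits <= from & to <= hits + nchar(peptide) - 1L)
  }

  category <- vapply(ssdb_only, function(p) {
    if (any(grepl(p, reference_proteome$sequence, fixed = TRUE)))
      return("reference_recovered")
    if (nrow(sav) > 0L) {
      for (i in seq_len(nrow(sav))) {
        if (covers(p, sav$sequence[i], sav_tags$position[i],
                   sav_tags$position[i]))
          return("SAV")
      }
    }
    if (nrow(sj) > 0L) {
      for (i in seq_len(nrow(sj))) {
        if (covers(p, sj$sequence[i], sj_tags$span_from[i],
                   sj_tags$span_to[i]))
          return("novel_SJ")
      }
    }
    # fallback: peptides that map to a variant or junction record without
    # meeting its coverage condition (e.g. a sub-peptide of an off-frame
    # junction polypeptide that stays on one side of the splice point)
    # still have that record as their only possible source
    if (nrow(sav) > 0L && any(grepl(p, sav$sequence, fixed = TRUE)))
      return("SAV")
    if (nrow(sj) > 0L && any(grepl(p, sj$sequence, fixed = TRUE)))
      return("novel_SJ")
    stop("SSdb-only peptide matches no database entry: ", p)
  }, "")

  structure(list(
    ssdb_only = data.frame(peptide = ssdb_only,
                           category = unname(category),
                           stringsAsFactors = FALSE),
    refdb_only = refdb_only,
    shared = shared,
    counts = c(ssdb_only = length(ssdb_only),
               refdb_only = length(refdb_only),
               shared = length(shared),
               novel_SJ = sum(category == "novel_SJ"),
               SAV = sum(category == "SAV"),
               reference_recovered = sum(category == "reference_recovered"))
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("comparison_result:\n")
  print(x$counts)
  invisible(x)
}

#' Per-sample and pooled set-comparison summary
#'
#' Counts the SSdb-only / REFdb-only / shared partition per sample and
#' pooled, and per category the total distinct peptides with the number
#' seen in two or more samples (the recurrence statistic).
#'
#' @param results Named list of `comparison_result` objects, one per
#'   sample.
#' @return List with `per_sample` (data frame of counts), `pooled`
#'   (counts over sample unions) and `recurrence` (per category: distinct
#'   peptides and how many recur in >= 2 samples).
#' @export
venn_summary <- function(results) {
  stopifnot(length(results) > 0L)
  per_sample <- do.call(rbind, lapply(names(results), function(s) {
    r <- results[[s]]
    data.frame(sample = s, t(r$counts), stringsAsFactors = FALSE)
  }))
  union_of <- function(get) sort(unique(unlist(lapply(results, get))))
  pooled_ss_only <- union_of(function(r) r$ssdb_only$peptide)
  pooled <- c(ssdb_only = length(pooled_ss_only),
              refdb_only = length(union_of(function(r) r$refdb_only)),
              shared = length(union_of(function(r) r$shared)))
  cats <- c("novel_SJ", "SAV", "reference_recovered")
  recurrence <- do.call(rbind, lapply(cats, function(cat) {
    peptide_lists <- lapply(results, function(r)
      r$ssdb_only$peptide[r$ssdb_only$category == cat])
    all_p <- unlist(peptide_lists)
    n_samples <- table(unlist(lapply(peptide_lists, unique)))
    data.frame(category = cat,
               distinct_peptides = length(unique(all_p)),
               seen_in_2plus = sum(n_samples >= 2L),
               stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, pooled = pooled, recurrence = recurrence)
}

#' Write per-category peptide lists as TSV
#'
#' Emits the SSdb-only peptides with their categories, and the REFdb-only
#' peptide list, for downstream inspection.
#'
#' @param result A `comparison_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_comparison_tables <- function(result, dir, prefix = "comparison") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_ssdb_only.tsv"))
  utils::write.table(result$ssdb_only, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_refdb_only.tsv"))
  utils::write.table(data.frame(peptide = result$refdb_only), p2,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
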