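#' Assemble a search database from the three record streams
#'
#' Concatenates the reference, SAV and SJ entry streams (in that order)
#' into one sample-specific search database. Exact duplicate sequences
#' within a stream are retained once with merged provenance; SAV or SJ
#' entries whose sequence is identical to a reference entry are flagged
#' and dropped (they carry no new evidence). Accession collisions are
#' re-suffixed deterministically. A reference-only database (REFdb) is the
#' degenerate call with empty SAV and SJ streams.
#'
#' @param ref_entries,sav_entries,sj_entries `protein_entries` streams
#'   (any may be empty or `NULL`).
#' @param name Database name.
#' @return A `search_db` object: list with `name`, `entries`, `counts`,
#'   `has_decoys` and an assembly `report`.
#' @export
assemble_database <- function(ref_entries = NULL, sav_entries = NULL,
                              sj_entries = NULL, name = "db") {
  empty <- protein_entries(character(), character())
  streams <- list(REF = ref_entries %||% empty,
                  SAV = sav_entries %||% empty,
                  SJ = sj_entries %||% empty)
  for (o in names(streams)) {
    s <- streams[[o]]
    if (nrow(s) && !all(s$origin == o))
      stop("stream ", o, " contains entries of a different origin")
  }
  report <- list(dedup_within = 0L, dropped_vs_ref = 0L, collisions = 0L)

  dedup <- function(s) {
    if (nrow(s) < 2L) return(s)
    first <- !duplicated(s$sequence)
    if (all(first)) return(s)
    merged <- tapply(s$provenance, s$sequence, function(p)
      paste(unique(p), collapse = ","))
    out <- s[first, , drop = FALSE]
    out$provenance <- unname(merged[out$sequence])
    report$dedup_within <<- report$dedup_within + sum(!first)
    out
  }
  streams <- lapply(streams, dedup)

  ref_seqs <- streams$REF$sequence
  for (o in c("SAV", "SJ")) {
    dup <- streams[[o]]$sequence %in% ref_seqs
    if (any(dup)) {
      report$dropped_vs_ref <- report$dropped_vs_ref + sum(dup)
      streams[[o]] <- streams[[o]][!dup, , drop = FALSE]
    }
  }

  entries <- rbind(streams$REF, streams$SAV, streams$SJ)
  if (nrow(entries) == 0L) stop("empty database: no entries in any stream")
  # deterministic re-suffixing of accession collisions
  while (anyDuplicated(entries$accession)) {
    d <- duplicated(entries$accession)
    entries$accession[d] <- paste0(entries$accession[d], "_2")
    report$collisions <- report$collisions + sum(d)
  }
  rownames(entries) <- NULL
  class(entries) <- c("protein_entries", "data.frame")
  validate_protein_entries(entries)
  counts <- table(factor(entries$origin, levels = .ORIGINS))
  structure(list(name = name, entries = entries,
                 counts = as.integer(counts[c("REF", "SAV", "SJ", "DECOY")]) |>
                   stats::setNames(c("REF", "SAV", "SJ", "DECOY")),
                 has_decoys = FALSE, report = report),
            class = "search_db")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.search_db <- function(x, ...) {
  cat(sprintf("search_db '%s': %d entries (REF %d, SAV %d, SJ %d, DECOY %d)%s\n",
              x$name, nrow(x$entries), x$counts[["REF"]], x$counts[["SAV"]],
              x$counts[["SJ"]], x$counts[["DECOY"]],
              if (x$has_decoys) ", decoys appended" else ""))
  invisible(x)
}

#' Append reversed decoys to a search database
#'
#' Adds one decoy per target entry: the full character-reversed sequence
#' under the accession `DECOY_<target accession>`. Decoys make the
#' empirical target-decoy FDR estimate possible; full reversal preserves
#' the length distribution and amino-acid composition of the target set
#' exactly. Palindromic targets (decoy identical to target) are allowed
#' and flagged in the report.
#'
#' @param db A `search_db` without decoys.
#' @return The database with `2n` entries.
#' @export
add_decoys <- function(db) {
  stopifnot(inherits(db, "search_db"))
  if (db$has_decoys || any(db$entries$origin == "DECOY"))
    stop("database already contains decoys")
  t <- db$entries
  rev_seq <- vapply(strsplit(t$sequence, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), "")
  decoys <- protein_entries(accession = paste0("DECOY_", t$accession),
                            sequence = rev_seq, origin = "DECOY",
                            provenance = t$provenance,
                            description = t$description,
                            target_origin = t$origin)
  db$report$palindromic_decoys <- sum(rev_seq == t$sequence)
  entries <- rbind(t, decoys)
  rownames(entries) <- NULL
  class(entries) <- c("protein_entries", "data.frame")
  db$entries <- entries
  db$counts[["DECOY"]] <- nrow(decoys)
  db$has_decoys <- TRUE
  db
}

#' Write an assembly report as TSV
#'
#' @param db A `search_db`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assembly_report <- function(db, path) {
  rep <- db$report
  df <- data.frame(
    metric = c("name", "n_ref", "n_sav", "n_sj", "n_decoy",
               "dedup_within", "dropped_vs_ref", "collisions"),
    value = c(db$name, db$counts[["REF"]], db$counts[["SAV"]],
              db$counts[["SJ"]], db$counts[["DECOY"]],
              rep$dedup_within, rep$dropped_vs_ref, rep$collisions),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
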