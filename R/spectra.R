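#' Read an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` (first
#' number = precursor m/z), optional `CHARGE` (e.g. `2+`) and `SCANS`
#' headers followed by `m/z intensity` peak lines. Peaks are sorted by
#' m/z; zero- or negative-intensity peaks are rejected.
#'
#' @param path MGF file.
#' @return List of spectra; each spectrum is a list with `title`, `scan`,
#'   `pepmass` (precursor m/z), `charge` (integer or `NA`), `mz` and
#'   `intensity` vectors.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  spectra <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    get <- function(key) {
      v <- hdr[startsWith(hdr, paste0(key, "="))]
      if (length(v)) sub(paste0("^", key, "="), "", v[1L]) else NA_character_
    }
    title <- get("TITLE")
    scan <- get("SCANS")
    if (is.na(scan)) scan <- if (!is.na(title)) title else as.character(k)
    pepmass <- as.numeric(strsplit(get("PEPMASS"), "\\s+")[[1L]][1L])
    charge_s <- get("CHARGE")
    charge <- if (is.na(charge_s)) NA_integer_
              else as.integer(sub("\\+$", "", charge_s))
    peaks <- block[!is_hdr & nzchar(block)]
    if (!length(peaks)) stop("spectrum ", scan, " has no peaks")
    mat <- do.call(rbind, lapply(strsplit(trimws(peaks), "\\s+"),
                                 function(x) as.numeric(x[1:2])))
    if (anyNA(mat)) stop("malformed peak line in spectrum ", scan)
    if (any(mat[, 2L] <= 0)) stop("non-positive intensity in spectrum ", scan)
    o <- order(mat[, 1L])
    spectra[[k]] <- list(title = title, scan = scan, pepmass = pepmass,
                         charge = charge, mz = mat[o, 1L],
                         intensity = mat[o, 2L])
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra List of spectra as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title) && !is.na(sp$title))
      writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con)
    if (!is.null(sp$charge) && !is.na(sp$charge))
      writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    if (!is.null(sp$scan) && !is.na(sp$scan))
      writeLines(paste0("SCANS=", sp$scan), con)
    writeLines(sprintf("%.6f %.4f", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Filter a spectrum to its most intense peaks
#'
#' Keeps the `max_peaks` most intense peaks (ties broken toward lower
#' m/z), re-sorted by m/z. Spectra with fewer peaks pass unchanged.
#'
#' @param spectrum A spectrum list.
#' @param settings A [search_settings()] object.
#' @return The filtered spectrum.
#' @export
preprocess_spectrum <- function(spectrum, settings = search_settings()) {
  n <- length(spectrum$mz)
  k <- settings$max_peaks
  if (n <= k) return(spectrum)
  o <- order(-spectrum$intensity, spectrum$mz)[seq_len(k)]
  o <- sort(o)  # peaks are stored m/z-sorted already
  spectrum$mz <- spectrum$mz[o]
  spectrum$intensity <- spectrum$intensity[o]
  spectrum
}
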