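#' Chromatogram objects
#'
#' A `chromatogram` holds one well's GC-MS run: an ordered vector of scan
#' retention times (minutes) and, per scan, a sparse centroided spectrum
#' (two-column matrix of m/z and intensity counts).
#'
#' @param well_id Plate-well identifier, e.g. `"A1"`.
#' @param rt Numeric vector of scan retention times in minutes.
#' @param spectra List (same length as `rt`) of two-column numeric matrices
#'   with columns `mz` and `intensity`. A scan with no ions is a 0-row matrix.
#' @param metadata Optional named list of free-text acquisition annotations.
#'
#' @return An object of class `chromatogram`.
#' @details Scans are sorted by retention time on construction (with a warning
#'   if the input was out of order). Retention times must be strictly
#'   increasing after sorting, intensities non-negative, and at least two
#'   scans present.
#' @export
chromatogram <- function(well_id, rt, spectra, metadata = list()) {
  stopifnot(is.character(well_id), length(well_id) == 1L)
  rt <- as.numeric(rt)
  if (length(rt) < 2L) {
    stop("empty or single-scan run: a chromatogram needs at least 2 scans",
         call. = FALSE)
  }
  if (length(spectra) != length(rt)) {
    stop("`rt` and `spectra` lengths differ", call. = FALSE)
  }
  spectra <- lapply(spectra, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 2L) stop("each spectrum must have columns mz, intensity",
                            call. = FALSE)
    colnames(s) <- c("mz", "intensity")
    storage.mode(s) <- "double"
    s
  })
  if (is.unsorted(rt, strictly = TRUE)) {
    warning("scans out of retention-time order; re-sorting", call. = FALSE)
    o <- order(rt)
    rt <- rt[o]
    spectra <- spectra[o]
  }
  if (anyDuplicated(rt)) {
    stop("duplicate scan retention times", call. = FALSE)
  }
  if (any(vapply(spectra, function(s) any(s[, "intensity"] < 0), logical(1)))) {
    stop("negative intensities are not allowed", call. = FALSE)
  }
  structure(
    list(well_id = well_id, rt = rt, spectra = spectra, metadata = metadata),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> well %s: %d scans, %.3f-%.3f min\n",
              x$well_id, length(x$rt), min(x$rt), max(x$rt)))
  invisible(x)
}

#' Read a per-well GC-MS run
#'
#' Reads one well's chromatogram from either an mzXML file (via
#' \pkg{mzR}/proteowizard bindings) or the package's plain scan-table dialect:
#' a tab-separated file with columns `scan_time_min`, `mz`, `intensity`, one
#' row per centroid, rows belonging to the same scan sharing a
#' `scan_time_min`. mzXML retention times are stored in seconds and converted
#' to minutes.
#'
#' @param path Path to an `.mzXML`/`.mzML` file or a `.tsv`/`.txt` scan table.
#' @param well_id Well identifier; defaults to the file name without
#'   extension.
#' @return A [chromatogram].
#' @export
read_mzxml <- function(path, well_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(well_id)) {
    well_id <- sub("\\.[^.]+$", "", basename(path))
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tsv", "txt")) {
    return(read_chrom_table(path, well_id = well_id))
  }
  ms <- tryCatch(
    mzR::openMSfile(path),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  on.exit(close(ms), add = TRUE)
  hdr <- tryCatch(
    mzR::header(ms),
    error = function(e) stop("cannot parse scan headers of '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  n <- nrow(hdr)
  if (n == 0L) stop("empty run: '", path, "' contains no scans", call. = FALSE)
  pks <- tryCatch(
    mzR::peaks(ms),
    error = function(e) stop("cannot decode peak data of '", path,
                             "' (first bad scan unknown): ",
                             conditionMessage(e), call. = FALSE)
  )
  if (n == 1L) pks <- list(pks)
  chromatogram(
    well_id = well_id,
    rt = hdr$retentionTime / 60,
    spectra = pks,
    metadata = list(source = path, format = "mzXML")
  )
}

#' @rdname read_mzxml
#' @export
read_chrom_table <- function(path, well_id = NULL) {
  if (is.null(well_id)) well_id <- sub("\\.[^.]+$", "", basename(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scan_time_min", "mz", "intensity")
  if (!all(need %in% names(tab))) {
    stop("scan table '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("empty run: '", path, "' has no scans",
                            call. = FALSE)
  times <- sort(unique(tab$scan_time_min))
  spectra <- lapply(times, function(t0) {
    sub <- tab[tab$scan_time_min == t0 & !is.na(tab$mz), c("mz", "intensity")]
    as.matrix(sub)
  })
  chromatogram(well_id, times, spectra,
               metadata = list(source = path, format = "table"))
}

#' Write a chromatogram as a plain scan table
#'
#' Writes the package's TSV dialect (`scan_time_min`, `mz`, `intensity`).
#' Scans with empty spectra are written as a single row with `mz` empty and
#' `intensity` 0 so that the scan grid survives a round trip.
#'
#' @param chrom A [chromatogram].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chrom_table <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  rows <- lapply(seq_along(chrom$rt), function(i) {
    s <- chrom$spectra[[i]]
    if (nrow(s) == 0L) {
      data.frame(scan_time_min = chrom$rt[i], mz = NA_real_, intensity = 0)
    } else {
      data.frame(scan_time_min = chrom$rt[i], mz = s[, "mz"],
                 intensity = s[, "intensity"])
    }
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total ion chromatogram
#'
#' Collapses each scan's spectrum to its total ion count: the sum of all
#' centroid intensities in the scan. Peak picking and integration downstream
#' operate on this series.
#'
#' @param chrom A [chromatogram].
#' @return A data frame with columns `rt` (minutes) and `intensity` (total
#'   counts), one row per scan, in retention-time order.
#' @export
total_ion_chromatogram <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  tic <- vapply(chrom$spectra, function(s) sum(s[, "intensity"]), numeric(1))
  data.frame(rt = chrom$rt, intensity = tic)
}
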