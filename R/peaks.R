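#' Compound reference tables
#'
#' The targeted screen quantifies a small panel of monoterpenes against
#' authentic-standard retention times and characteristic electron-impact
#' ions. A reference table has one row per compound with its expected
#' retention time (minutes), an RT matching tolerance, the primary
#' (most-intense diagnostic) ion, optional qualifier ions, a flag for
#' compounds masked by the extraction-solvent peak, and a flag marking the
#' internal standard.
#'
#' @param name Character vector of compound labels.
#' @param expected_rt,rt_tolerance Numeric, minutes. `rt_tolerance` must be
#'   positive; it defaults to 0.05 min, consistent with a short fast-GC
#'   method, and should be tuned per instrument.
#' @param primary_ion Numeric m/z of the primary ion.
#' @param qualifier_ions List of numeric vectors (or semicolon-separated
#'   strings) of additional diagnostic ions.
#' @param solvent_masked Logical; `TRUE` for analytes co-eluting with the
#'   solvent peak, which are never assigned or quantified.
#' @param is_internal_standard Logical; exactly one row must be `TRUE`.
#' @return A data frame of class `compound_refs` with a list-column
#'   `qualifier_ions`.
#' @export
compound_refs <- function(name, expected_rt, rt_tolerance = 0.05,
                          primary_ion, qualifier_ions = NULL,
                          solvent_masked = FALSE,
                          is_internal_standard = FALSE) {
  n <- length(name)
  if (is.null(qualifier_ions)) qualifier_ions <- rep(list(numeric(0)), n)
  if (is.character(qualifier_ions)) {
    qualifier_ions <- lapply(strsplit(qualifier_ions, ";"),
                             function(x) as.numeric(x[nzchar(x)]))
  }
  refs <- data.frame(
    name = as.character(name),
    expected_rt = as.numeric(expected_rt),
    rt_tolerance = rep_len(as.numeric(rt_tolerance), n),
    primary_ion = as.numeric(primary_ion),
    solvent_masked = rep_len(as.logical(solvent_masked), n),
    is_internal_standard = rep_len(as.logical(is_internal_standard), n),
    stringsAsFactors = FALSE
  )
  refs$qualifier_ions <- qualifier_ions
  if (any(refs$rt_tolerance <= 0)) stop("rt_tolerance must be > 0",
                                        call. = FALSE)
  if (sum(refs$is_internal_standard) != 1L) {
    stop("exactly one compound must be flagged is_internal_standard",
         call. = FALSE)
  }
  if (anyDuplicated(refs$name)) stop("duplicate compound names", call. = FALSE)
  class(refs) <- c("compound_refs", "data.frame")
  refs
}

#' @rdname compound_refs
#' @param path CSV file with header
#'   `name,expected_rt,rt_tolerance,primary_ion,qualifier_ions,solvent_masked,is_internal_standard`
#'   where `qualifier_ions` is semicolon-separated.
#' @export
read_compound_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(qualifier_ions = "character"))
  compound_refs(tab$name, tab$expected_rt, tab$rt_tolerance, tab$primary_ion,
                tab$qualifier_ions, tab$solvent_masked,
                tab$is_internal_standard)
}

#' Names of compounds quantified against thresholds
#'
#' Targeted compounds are all reference compounds that are neither the
#' internal standard nor masked by the solvent peak.
#'
#' @param refs A [compound_refs] table.
#' @return Character vector of compound names.
#' @export
targeted_compounds <- function(refs) {
  refs$name[!refs$is_internal_standard & !refs$solvent_masked]
}

# trapezoidal integral of y over x between indices i..j
trapezoid <- function(x, y, i, j) {
  if (j <= i) return(0)
  idx <- i:j
  sum(diff(x[idx]) * (y[idx][-1] + y[idx][-length(idx)]) / 2)
}

#' Pick peaks on a total ion chromatogram
#'
#' Detects local maxima on the TIC, filters them by topographic prominence
#' and minimum width, sets integration bounds at the nearest flanking local
#' minima (valley-to-valley), and integrates each peak by the trapezoidal
#' rule.
#'
#' @param tic Data frame from [total_ion_chromatogram()] (columns `rt`,
#'   `intensity`) with at least 3 scans.
#' @param min_prominence Minimum prominence in counts: the apex must rise at
#'   least this far above the higher of its two bounding valleys (measured
#'   against the lowest point between the apex and the nearest taller apex,
#'   or the series edge).
#' @param min_width_scans Minimum number of scans spanned valley-to-valley.
#' @return Data frame with one row per peak in retention-time order: columns
#'   `apex_idx`, `apex_rt`, `left_rt`, `right_rt`, `apex_intensity`,
#'   `prominence`, `area` (counts x min) and `compound` (`NA`, filled by
#'   [identify_peaks()]).
#' @export
pick_peaks <- function(tic, min_prominence = 100, min_width_scans = 3) {
  y <- tic$intensity
  x <- tic$rt
  n <- length(y)
  if (n < 3L) stop("insufficient data: peak picking needs at least 3 scans",
                   call. = FALSE)
  # candidate apices: strict rise on the left, non-rise on the right, so a
  # flat-topped peak yields a single apex at its first plateau scan
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(cand) == 0L) return(empty_peak_table())
  keep <- logical(length(cand))
  left <- right <- integer(length(cand))
  prom <- numeric(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # prominence: lowest point toward the nearest taller sample on each side
    li <- i
    lmin <- y[i]
    while (li > 1L && y[li - 1L] <= y[i]) {
      li <- li - 1L
      lmin <- min(lmin, y[li])
    }
    if (li == 1L) lmin <- min(y[1:i])
    ri <- i
    rmin <- y[i]
    while (ri < n && y[ri + 1L] <= y[i]) {
      ri <- ri + 1L
      rmin <- min(rmin, y[ri])
    }
    if (ri == n) rmin <- min(y[i:n])
    prom[k] <- y[i] - max(lmin, rmin)
    # integration bounds: walk downhill to the nearest flanking local minimum
    lb <- i
    while (lb > 1L && y[lb - 1L] <= y[lb]) lb <- lb - 1L
    rb <- i
    while (rb < n && y[rb + 1L] <= y[rb]) rb <- rb + 1L
    left[k] <- lb
    right[k] <- rb
    keep[k] <- prom[k] >= min_prominence && (rb - lb + 1L) >= min_width_scans
  }
  cand <- cand[keep]
  if (length(cand) == 0L) return(empty_peak_table())
  left <- left[keep]
  right <- right[keep]
  prom <- prom[keep]
  area <- vapply(seq_along(cand),
                 function(k) trapezoid(x, y, left[k], right[k]), numeric(1))
  data.frame(
    apex_idx = cand,
    apex_rt = x[cand],
    left_rt = x[left],
    right_rt = x[right],
    apex_intensity = y[cand],
    prominence = prom,
    area = area,
    compound = NA_character_,
    stringsAsFactors = FALSE
  )
}

empty_peak_table <- function() {
  data.frame(apex_idx = integer(0), apex_rt = numeric(0),
             left_rt = numeric(0), right_rt = numeric(0),
             apex_intensity = numeric(0), prominence = numeric(0),
             area = numeric(0), compound = character(0),
             stringsAsFactors = FALSE)
}

#' Assign picked peaks to reference compounds
#'
#' A peak can be assigned to a compound when its apex retention time falls
#' within the compound's RT window and, at the apex scan, the most intense
#' ion among the compound's primary + qualifier ions (m/z matched within
#' `mz_tol`) is the primary ion. Assignment is a partial matching: every
#' compound goes to at most one peak and vice versa, with candidate pairs
#' taken in order of increasing |RT difference| (ties broken by
#' reference-table order). Solvent-masked compounds are never assigned.
#'
#' @param peaks Peak table from [pick_peaks()].
#' @param chrom The [chromatogram] the peaks came from (for apex spectra).
#' @param refs A [compound_refs] table.
#' @param mz_tol m/z matching tolerance for ion lookup (default 0.3).
#' @return The peak table with `compound` filled in where matched.
#' @export
identify_peaks <- function(peaks, chrom, refs, mz_tol = 0.3) {
  stopifnot(inherits(refs, "compound_refs"))
  if (nrow(refs) == 0L) stop("empty reference table", call. = FALSE)
  if (nrow(peaks) == 0L) return(peaks)
  open_refs <- which(!refs$solvent_masked)
  cand <- list()
  for (r in open_refs) {
    drt <- abs(peaks$apex_rt - refs$expected_rt[r])
    for (p in which(drt <= refs$rt_tolerance[r])) {
      spec <- chrom$spectra[[peaks$apex_idx[p]]]
      if (!primary_ion_confirmed(spec, refs$primary_ion[r],
                                 refs$qualifier_ions[[r]], mz_tol)) next
      cand[[length(cand) + 1L]] <- c(peak = p, ref = r, drt = drt[p])
    }
  }
  if (length(cand) == 0L) return(peaks)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "drt"], cand[, "ref"]), , drop = FALSE]
  used_peak <- logical(nrow(peaks))
  used_ref <- logical(nrow(refs))
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, "peak"]
    r <- cand[k, "ref"]
    if (used_peak[p] || used_ref[r]) next
    peaks$compound[p] <- refs$name[r]
    used_peak[p] <- TRUE
    used_ref[r] <- TRUE
  }
  peaks
}

# TRUE when, among the listed ions present in the spectrum, the primary ion
# is the most intense; FALSE when the primary ion itself is absent
primary_ion_confirmed <- function(spectrum, primary_ion, qualifier_ions,
                                  mz_tol) {
  if (nrow(spectrum) == 0L) return(FALSE)
  ion_intensity <- function(ion) {
    hit <- abs(spectrum[, "mz"] - ion) <= mz_tol
    if (!any(hit)) return(NA_real_)
    max(spectrum[hit, "intensity"])
  }
  pri <- ion_intensity(primary_ion)
  if (is.na(pri)) return(FALSE)
  quals <- vapply(qualifier_ions, ion_intensity, numeric(1))
  all(is.na(quals) | quals <= pri)
}

#' Per-well quantification against the internal standard
#'
#' Divides every assigned compound's integrated TIC area by the internal
#' standard's area in the same well, correcting injection-to-injection
#' variability. Targeted compounds without an assigned peak are reported as
#' 0 and flagged `is_missing`; solvent-masked compounds are reported as `NA`
#' and flagged `is_masked`. A well whose internal-standard peak is absent or
#' has zero area is marked `failed` and carries no normalized areas; failed
#' wells are excluded from all downstream statistics.
#'
#' @param peaks Identified peak table from [identify_peaks()].
#' @param refs A [compound_refs] table.
#' @param well_id Well identifier.
#' @param role One of `"sample"`, `"parent_control"`, `"solvent_control"`.
#' @return An object of class `well_result`: a list with `well_id`, `role`,
#'   `status` (`"ok"`/`"failed"`), `is_area`, named numeric
#'   `normalized_area`, raw `area`, and a per-compound `flags` data frame.
#' @export
normalize_well <- function(peaks, refs, well_id,
                           role = c("sample", "parent_control",
                                    "solvent_control")) {
  role <- match.arg(role)
  stopifnot(inherits(refs, "compound_refs"))
  is_name <- refs$name[refs$is_internal_standard]
  is_row <- peaks[!is.na(peaks$compound) & peaks$compound == is_name, ,
                  drop = FALSE]
  compounds <- refs$name[!refs$is_internal_standard]
  masked <- refs$solvent_masked[match(compounds, refs$name)]
  if (nrow(is_row) == 0L || is_row$area[1] <= 0) {
    res <- list(well_id = well_id, role = role, status = "failed",
                error = "internal standard peak missing or zero area",
                is_area = NA_real_,
                normalized_area = stats::setNames(rep(NA_real_,
                                                      length(compounds)),
                                                  compounds),
                area = stats::setNames(rep(NA_real_, length(compounds)),
                                       compounds),
                flags = well_flags(compounds, masked,
                                   is_missing = rep(NA, length(compounds))))
    class(res) <- "well_result"
    return(res)
  }
  is_area <- is_row$area[1]
  raw <- stats::setNames(rep(0, length(compounds)), compounds)
  for (i in seq_len(nrow(peaks))) {
    cpd <- peaks$compound[i]
    if (!is.na(cpd) && cpd %in% compounds) raw[cpd] <- peaks$area[i]
  }
  norm <- raw / is_area
  missing <- raw == 0 & !masked
  raw[masked] <- NA_real_
  norm[masked] <- NA_real_
  res <- list(well_id = well_id, role = role, status = "ok",
              is_area = is_area, normalized_area = norm, area = raw,
              flags = well_flags(compounds, masked, missing))
  class(res) <- "well_result"
  res
}

well_flags <- function(compounds, masked, is_missing) {
  data.frame(compound = compounds, is_masked = masked,
             is_missing = is_missing, below_threshold = NA,
             stringsAsFactors = FALSE)
}

#' @export
print.well_result <- function(x, ...) {
  cat(sprintf("<well_result> %s (%s, %s)\n", x$well_id, x$role, x$status))
  if (x$status == "ok") print(round(x$normalized_area, 4))
  invisible(x)
}

#' Background thresholds from solvent-only control wells
#'
#' The active-variant threshold for each targeted compound is the arithmetic
#' mean of its normalized area over the plate's solvent-only control wells
#' (the average background signal). Thresholds are per plate; failed wells
#' are ignored.
#'
#' @param solvent_wells List of `well_result`s with role `solvent_control`.
#' @param compounds Character vector of targeted compound names (defaults to
#'   all non-masked compounds present in the first well).
#' @return Named numeric vector of per-compound thresholds (class
#'   `threshold_set`).
#' @export
compute_thresholds <- function(solvent_wells, compounds = NULL) {
  solvent_wells <- Filter(function(w) w$status == "ok", solvent_wells)
  if (length(solvent_wells) == 0L) {
    stop("no usable solvent-control wells: thresholds undefined",
         call. = FALSE)
  }
  if (is.null(compounds)) {
    w1 <- solvent_wells[[1]]
    compounds <- w1$flags$compound[!w1$flags$is_masked]
  }
  vals <- vapply(solvent_wells,
                 function(w) w$normalized_area[compounds], numeric(length(compounds)))
  vals <- matrix(vals, nrow = length(compounds))
  thr <- rowMeans(vals)
  names(thr) <- compounds
  structure(thr, class = c("threshold_set", "numeric"))
}

#' Run the whole per-well quantification chain
#'
#' Convenience wrapper: TIC, peak picking, identification and
#' internal-standard normalization for one well.
#'
#' @inheritParams pick_peaks
#' @inheritParams identify_peaks
#' @inheritParams normalize_well
#' @param chrom A [chromatogram].
#' @return A `well_result` (see [normalize_well()]).
#' @export
process_well <- function(chrom, refs, role = "sample",
                         min_prominence = 100, min_width_scans = 3,
                         mz_tol = 0.3) {
  tic <- total_ion_chromatogram(chrom)
  pk <- pick_peaks(tic, min_prominence = min_prominence,
                   min_width_scans = min_width_scans)
  pk <- identify_peaks(pk, chrom, refs, mz_tol = mz_tol)
  normalize_well(pk, refs, well_id = chrom$well_id, role = role)
}

#' Export per-well peak quantification as a table
#'
#' @param wells List of `well_result`s.
#' @return Data frame `well_id, role, status, compound, area,
#'   normalized_area, is_masked, is_missing` suitable for `write.csv`.
#' @export
well_table <- function(wells) {
  rows <- lapply(wells, function(w) {
    data.frame(well_id = w$well_id, role = w$role, status = w$status,
               compound = w$flags$compound,
               area = unname(w$area[w$flags$compound]),
               normalized_area = unname(w$normalized_area[w$flags$compound]),
               is_masked = w$flags$is_masked,
               is_missing = w$flags$is_missing,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
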