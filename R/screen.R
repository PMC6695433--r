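#' Read a plate layout table
#'
#' Layout CSV with header `plate_id,well_id,role,library_id`; `role` is one
#' of `sample`, `parent_control`, `solvent_control`. Every plate must carry
#' at least one parent control (the parent enzyme re-screened on each plate)
#' and one solvent-only control.
#'
#' @param path CSV file path.
#' @return Data frame with those four columns.
#' @export
read_plate_layout <- function(path) {
  lay <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well_id", "role", "library_id")
  if (!all(need %in% names(lay))) {
    stop("layout must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_layout(lay)
  lay
}

validate_layout <- function(lay) {
  bad <- setdiff(lay$role, c("sample", "parent_control", "solvent_control"))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (p in unique(lay$plate_id)) {
    sub <- lay[lay$plate_id == p, ]
    if (anyDuplicated(sub$well_id)) {
      stop("duplicate well ids on plate ", p, call. = FALSE)
    }
    if (!any(sub$role == "parent_control") ||
        !any(sub$role == "solvent_control")) {
      stop("plate ", p, " lacks a parent_control or solvent_control well",
           call. = FALSE)
    }
  }
  invisible(lay)
}

#' Call a well active or inactive
#'
#' A clone is active when at least one non-masked targeted compound's
#' normalized area is strictly above the plate's background threshold for
#' that compound. Masked compounds never contribute.
#'
#' @param well A `well_result` (must not be failed).
#' @param thresholds Named per-compound thresholds from
#'   [compute_thresholds()].
#' @return Logical scalar.
#' @export
call_active <- function(well, thresholds) {
  if (well$status != "ok") {
    stop("active call undefined for failed well ", well$well_id,
         call. = FALSE)
  }
  cpds <- intersect(names(thresholds),
                    well$flags$compound[!well$flags$is_masked])
  any(well$normalized_area[cpds] > thresholds[cpds], na.rm = TRUE)
}

#' Fold change of a well over the plate's parent controls
#'
#' Ratio of the well's normalized area for one compound to the median
#' normalized area of the same plate's parent-control wells. When the parent
#' median is 0 the ratio is `Inf` if the sample signal is positive and, by
#' convention, 1 if both are 0; both cases carry a `flag` attribute
#' (`"parent_zero"` / `"both_zero"`).
#'
#' @param well A `well_result`.
#' @param parent_wells List of `well_result`s with role `parent_control`
#'   from the same plate (failed wells ignored).
#' @param compound Compound name.
#' @return Numeric scalar with attribute `flag` (`"ok"` unless degenerate).
#' @export
fold_change <- function(well, parent_wells, compound) {
  parent_wells <- Filter(function(w) w$status == "ok", parent_wells)
  if (length(parent_wells) == 0L) {
    stop("no usable parent-control wells on this plate", call. = FALSE)
  }
  pv <- vapply(parent_wells, function(w) w$normalized_area[[compound]],
               numeric(1))
  if (all(is.na(pv))) {
    stop("compound ", compound, " not recorded in parent wells",
         call. = FALSE)
  }
  ref <- stats::median(pv, na.rm = TRUE)
  x <- well$normalized_area[[compound]]
  if (is.na(x)) return(structure(NA_real_, flag = "masked"))
  if (ref == 0) {
    if (x == 0) return(structure(1, flag = "both_zero"))
    return(structure(Inf, flag = "parent_zero"))
  }
  structure(unname(x / ref), flag = "ok")
}

#' Summarize fold changes for one library
#'
#' Per-compound median and quartiles of the fold-change distribution over a
#' library's usable sample wells. Quantiles use linear interpolation between
#' order statistics (`quantile type 7`). Infinite fold changes (parent
#' median zero) are excluded from the quantiles and counted separately.
#'
#' @param fc Data frame with columns `well_id`, `compound`, `fold_change`.
#' @param library_id Library label for the output.
#' @return Data frame `library_id, compound, n, n_infinite, lower_quartile,
#'   median, upper_quartile`; `n = 0` rows (with a warning) when a compound
#'   has no usable values.
#' @export
summarize_library <- function(fc, library_id) {
  if (nrow(fc) == 0L) {
    warning("no usable wells for library ", library_id, call. = FALSE)
    return(data.frame(library_id = library_id, compound = character(0),
                      n = integer(0), n_infinite = integer(0),
                      lower_quartile = numeric(0), median = numeric(0),
                      upper_quartile = numeric(0)))
  }
  rows <- lapply(split(fc, fc$compound), function(sub) {
    v <- sub$fold_change
    v <- v[!is.na(v)]
    inf <- sum(is.infinite(v))
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      warning("library ", library_id, ", compound ", sub$compound[1],
              ": no finite fold changes", call. = FALSE)
      return(data.frame(library_id = library_id, compound = sub$compound[1],
                        n = 0L, n_infinite = inf,
                        lower_quartile = NA_real_, median = NA_real_,
                        upper_quartile = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(library_id = library_id, compound = sub$compound[1],
               n = length(v), n_infinite = inf,
               lower_quartile = q[1], median = q[2], upper_quartile = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plate-level screening analytics
#'
#' Given all processed wells of one plate and its layout, derives background
#' thresholds from the solvent-only wells, calls every sample well active or
#' inactive, and computes per-compound fold changes over the plate's
#' parent-control median.
#'
#' @param wells Named list of `well_result`s (names or `well_id`s matching
#'   the layout).
#' @param layout Layout data frame for one plate (see [read_plate_layout()]).
#' @param compounds Targeted compound names; defaults to all non-masked
#'   compounds of the first usable well.
#' @return A list with `thresholds`, `calls` (data frame `well_id,
#'   library_id, active`), `fold_changes` (data frame `well_id, library_id,
#'   compound, fold_change, flag`) and `summaries` (one [summarize_library()]
#'   row set per library).
#' @export
screen_plate <- function(wells, layout, compounds = NULL) {
  validate_layout(layout)
  ids <- vapply(wells, `[[`, character(1), "well_id")
  names(wells) <- ids
  layout <- layout[layout$well_id %in% ids, , drop = FALSE]
  get_role <- function(role) wells[layout$well_id[layout$role == role]]
  solvent <- get_role("solvent_control")
  parents <- Filter(function(w) w$status == "ok", get_role("parent_control"))
  thresholds <- compute_thresholds(solvent, compounds)
  cpds <- names(thresholds)

  sample_rows <- layout[layout$role == "sample", , drop = FALSE]
  usable <- vapply(wells[sample_rows$well_id], function(w) w$status == "ok",
                   logical(1))
  calls <- data.frame(
    well_id = sample_rows$well_id,
    library_id = sample_rows$library_id,
    active = NA,
    stringsAsFactors = FALSE
  )
  calls$active[usable] <- vapply(wells[sample_rows$well_id[usable]],
                                 call_active, logical(1),
                                 thresholds = thresholds)
  fc_rows <- lapply(sample_rows$well_id[usable], function(id) {
    w <- wells[[id]]
    lib <- sample_rows$library_id[sample_rows$well_id == id]
    vals <- lapply(cpds, function(cpd) fold_change(w, parents, cpd))
    data.frame(well_id = id, library_id = lib, compound = cpds,
               fold_change = vapply(vals, as.numeric, numeric(1)),
               flag = vapply(vals, attr, character(1), "flag"),
               stringsAsFactors = FALSE)
  })
  fold_changes <- if (length(fc_rows)) do.call(rbind, fc_rows) else
    data.frame(well_id = character(0), library_id = character(0),
               compound = character(0), fold_change = numeric(0),
               flag = character(0))
  summaries <- do.call(rbind, lapply(split(fold_changes,
                                           fold_changes$library_id),
                                     function(sub)
                                       summarize_library(sub,
                                                         sub$library_id[1])))
  rownames(summaries) <- NULL
  list(thresholds = thresholds, calls = calls, fold_changes = fold_changes,
       summaries = summaries)
}
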