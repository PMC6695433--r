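#' Relative product profile of a variant
#'
#' Normalizes per-compound titres (or normalized peak areas) to fractions
#' summing to 1. A variant that made nothing has no defined profile and is
#' an error — it is inactive, not a profile of zeros.
#'
#' @param titres Named non-negative numeric vector, compound -> amount.
#' @return Named numeric vector of fractions (sums to 1; zero-titre
#'   compounds retained at 0).
#' @export
relative_profile <- function(titres) {
  titres <- unlist(titres)
  if (is.null(names(titres)) || any(!nzchar(names(titres)))) {
    stop("titres must be a named vector", call. = FALSE)
  }
  if (any(titres < 0)) stop("negative titres", call. = FALSE)
  total <- sum(titres)
  if (total <= 0) {
    stop("no product detected: relative profile undefined for an inactive variant",
         call. = FALSE)
  }
  titres / total
}

#' Euclidean distance between two product profiles
#'
#' Square root of the summed squared differences of product fractions,
#' taken over the union of both profiles' compounds (a compound absent from
#' one profile contributes its full fraction in the other). A distance of 0
#' means the two variants have the same product distribution; profiles
#' shifted entirely onto different products approach sqrt(2).
#'
#' @param p,ref Named fraction vectors (see [relative_profile()]).
#' @return Non-negative numeric scalar.
#' @export
euclidean_distance <- function(p, ref) {
  keys <- union(names(p), names(ref))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  rv <- ifelse(keys %in% names(ref), ref[keys], 0)
  pv[is.na(pv)] <- 0
  rv[is.na(rv)] <- 0
  sqrt(sum((pv - rv)^2))
}

#' Observed residues at one randomized position
#'
#' Bundles the observation counts of amino acids seen among sequenced active
#' variants at one target position, together with the template residue
#' there. Residues outside the degenerate codon's repertoire (other than the
#' template residue itself) cannot arise from a validated read and are
#' rejected.
#'
#' @param position 1-based amino-acid position.
#' @param counts Named non-negative integer vector, residue -> count.
#' @param template_residue One-letter template residue at the position.
#' @param design Optional [library_design] used to validate the support.
#' @return Object of class `position_observations`.
#' @export
position_observations <- function(position, counts, template_residue,
                                  design = NULL) {
  counts <- unlist(counts)
  if (length(counts) && (is.null(names(counts)) || any(counts < 0))) {
    stop("counts must be a named non-negative vector", call. = FALSE)
  }
  if (!is.null(design)) {
    allowed <- c(design$expansion$residues, template_residue)
    bad <- setdiff(names(counts), allowed)
    if (length(bad)) {
      stop("residues not encodable by ", design$degenerate_codon, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(position = as.integer(position), counts = counts,
                 template_residue = template_residue),
            class = "position_observations")
}

#' Plasticity score of a randomized position
#'
#' Histogram intersection between the observed mutant-residue distribution
#' and a uniform distribution over the degenerate codon's residue
#' repertoire. With K encodable residues (K = 11 for NBT) and f the
#' frequency distribution of observed non-parent residues, the score is
#' sum over residues of min(f, 1/K): 1 when every encodable residue is
#' observed equally often, 0 when no mutations were observed at the
#' position, in between when observations concentrate on few residues.
#' Parent-residue observations (including synonymous codon changes) carry no
#' information about tolerated substitutions and are excluded.
#'
#' @param obs A [position_observations] (or bare named count vector, in
#'   which case `template_residue` is taken as absent).
#' @param design A [library_design] supplying the residue repertoire.
#' @return Numeric scalar in [0, 1].
#' @export
plasticity_score <- function(obs, design) {
  stopifnot(inherits(design, "library_design"))
  support <- design$expansion$residues
  K <- length(support)
  if (K == 0L) stop("degenerate codon encodes no residues", call. = FALSE)
  counts <- if (inherits(obs, "position_observations")) {
    obs$counts[setdiff(names(obs$counts), obs$template_residue)]
  } else {
    unlist(obs)
  }
  counts <- counts[names(counts) %in% support]
  total <- sum(counts)
  if (length(counts) == 0L || total == 0) return(0)
  f <- stats::setNames(rep(0, K), support)
  f[names(counts)] <- counts / total
  sum(pmin(f, 1 / K))
}

#' Amino-acid occurrence tables
#'
#' Relative occurrence of mutant residues among sequenced active variants,
#' per randomized position and across the whole screen.
#'
#' @param records Variant-call rows ([call_variant()] format) over all
#'   wells; parent calls are excluded.
#' @return List of two data frames. `per_position`: `position, amino_acid,
#'   count, frequency, percent` (percent rounded to 0.1); `global`:
#'   `amino_acid, count, frequency, percent`. Positions with no mutant
#'   observations are omitted with a warning.
#' @export
aa_occurrence <- function(records) {
  mut <- records[!records$is_parent, , drop = FALSE]
  if (nrow(mut) == 0L) stop("no mutant observations", call. = FALSE)
  empty <- setdiff(unique(records$position), unique(mut$position))
  if (length(empty)) {
    warning("no mutant observations at position(s) ",
            paste(empty, collapse = ", "), "; omitted", call. = FALSE)
  }
  per_pos <- do.call(rbind, lapply(split(mut, mut$position), function(sub) {
    tab <- table(sub$amino_acid)
    data.frame(position = sub$position[1], amino_acid = names(tab),
               count = as.integer(tab),
               frequency = as.numeric(tab) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  per_pos$percent <- round(100 * per_pos$frequency, 1)
  rownames(per_pos) <- NULL
  gtab <- table(mut$amino_acid)
  global <- data.frame(amino_acid = names(gtab), count = as.integer(gtab),
                       frequency = as.numeric(gtab) / nrow(mut),
                       stringsAsFactors = FALSE)
  global$percent <- round(100 * global$frequency, 1)
  list(per_position = per_pos, global = global)
}

#' Library coverage probability
#'
#' For a single-position library built from a degenerate codon with
#' `n_codons` equiprobable codons, screened by picking `n_colonies`
#' independent colonies: the probability that one given codon is
#' represented at least once, `1 - ((K-1)/K)^n`, and the probability that
#' every codon is represented, by inclusion-exclusion
#' `sum_j (-1)^j C(K,j) ((K-j)/K)^n`. Screening 40 colonies of a 12-codon
#' NBT library puts the per-variant probability above 0.95.
#'
#' @param n_colonies Number of colonies screened (>= 0).
#' @param n_codons Number of codons in the degenerate expansion (>= 1).
#' @return List with `per_variant` and `all_variants` probabilities.
#' @export
coverage_probability <- function(n_colonies, n_codons) {
  stopifnot(n_colonies >= 0, n_codons >= 1)
  K <- n_codons
  n <- n_colonies
  per_variant <- 1 - ((K - 1) / K)^n
  j <- 0:K
  all_variants <- sum((-1)^j * choose(K, j) * ((K - j) / K)^n)
  if (n == 0) all_variants <- if (K == 0) 1 else 0
  list(per_variant = per_variant, all_variants = max(0, min(1, all_variants)))
}

#' Score every variant's profile distance and every position's plasticity
#'
#' Joins variant calls with per-well product profiles and produces the two
#' sequence-function tables of the screen: per-variant Euclidean distance to
#' the parent profile and per-position plasticity score.
#'
#' @param records Variant-call rows over all sequenced wells.
#' @param profiles Data frame `well_id, compound, titre` (titres or
#'   normalized areas) for the same wells.
#' @param parent_profile Named fraction vector for the parent enzyme
#'   ([relative_profile()] output).
#' @param design The [library_design].
#' @return List with `distances` (`well_id, variant_key,
#'   euclidean_distance`, distances also rounded to 3 decimals in
#'   `euclidean_distance_3dp`) and `plasticity` (`position,
#'   plasticity_score`).
#' @export
score_variants <- function(records, profiles, parent_profile, design) {
  wells <- unique(records$well_id)
  dist_rows <- lapply(wells, function(id) {
    sub <- profiles[profiles$well_id == id & !is.na(profiles$titre), ,
                    drop = FALSE]
    if (nrow(sub) == 0L || sum(sub$titre) <= 0) return(NULL)
    prof <- relative_profile(stats::setNames(sub$titre, sub$compound))
    rec <- records[records$well_id == id & !records$is_parent, ,
                   drop = FALSE]
    key <- if (nrow(rec)) paste(rec$variant_key, collapse = "+") else "parent"
    data.frame(well_id = id, variant_key = key,
               euclidean_distance = euclidean_distance(prof, parent_profile),
               stringsAsFactors = FALSE)
  })
  distances <- do.call(rbind, dist_rows)
  if (!is.null(distances)) {
    distances$euclidean_distance_3dp <- round(distances$euclidean_distance, 3)
  }
  tpl_aa <- strsplit(translate_cds(design$template_cds), "")[[1]]
  plasticity <- do.call(rbind, lapply(design$target_positions, function(p) {
    sub <- records[records$position == p & !records$is_parent, , drop = FALSE]
    obs <- position_observations(p, table(sub$amino_acid), tpl_aa[p])
    data.frame(position = p, plasticity_score = plasticity_score(obs, design))
  }))
  list(distances = distances, plasticity = plasticity)
}
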