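#' Degenerate-codon library designs
#'
#' A library design is a template coding sequence plus the 1-based
#' amino-acid positions that were randomized and the 3-letter IUPAC
#' degenerate codon introduced there (e.g. `NBT`, which expands to 12 codons
#' encoding 11 residues and deliberately avoids charged residues other than
#' Arg).
#'
#' @param template_cds Template coding sequence (character or
#'   `Biostrings::DNAString`), length divisible by 3, plain ACGT only.
#' @param target_positions Integer vector of 1-based amino-acid positions.
#' @param degenerate_codon 3-letter IUPAC string, default `"NBT"`.
#' @return An object of class `library_design` with the precomputed codon
#'   expansion (`$expansion`, see [expand_degenerate_codon()]).
#' @export
library_design <- function(template_cds, target_positions,
                           degenerate_codon = "NBT") {
  template_cds <- toupper(as.character(template_cds))
  if (nchar(template_cds) %% 3 != 0) {
    stop("template length not divisible by 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", template_cds)) {
    stop("template must contain plain A/C/G/T only", call. = FALSE)
  }
  n_aa <- nchar(template_cds) / 3
  target_positions <- sort(unique(as.integer(target_positions)))
  if (length(target_positions) == 0L ||
      any(target_positions < 1L | target_positions > n_aa)) {
    stop("target positions must lie in 1..", n_aa, call. = FALSE)
  }
  exp <- expand_degenerate_codon(degenerate_codon)
  structure(
    list(template_cds = template_cds,
         target_positions = target_positions,
         degenerate_codon = toupper(degenerate_codon),
         expansion = exp,
         n_aa = n_aa),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf(
    "<library_design> %d-codon template; %s at position(s) %s (%d codons, %d residues)\n",
    x$n_aa, x$degenerate_codon,
    paste(x$target_positions, collapse = ", "),
    length(x$expansion$codons), length(x$expansion$residues)))
  invisible(x)
}

#' Read a library design from a design file plus template FASTA
#'
#' The design file is YAML or CSV with fields `template_id`, `positions`
#' (comma-separated amino-acid positions) and `degenerate_codon`; the
#' template CDS is looked up by `template_id` in the FASTA.
#'
#' @param design_path YAML (`.yml`/`.yaml`) or CSV design file.
#' @param template_fasta FASTA file containing the template CDS.
#' @return A [library_design].
#' @export
read_library_design <- function(design_path, template_fasta) {
  ext <- tolower(sub(".*\\.", "", design_path))
  if (ext %in% c("yml", "yaml")) {
    d <- yaml::read_yaml(design_path)
  } else {
    d <- as.list(utils::read.csv(design_path, stringsAsFactors = FALSE)[1, ])
  }
  positions <- as.integer(strsplit(as.character(d$positions), ",")[[1]])
  seqs <- Biostrings::readDNAStringSet(template_fasta)
  hit <- match(d$template_id, sub("\\s.*", "", names(seqs)))
  if (is.na(hit)) {
    stop("template '", d$template_id, "' not found in ", template_fasta,
         call. = FALSE)
  }
  library_design(as.character(seqs[[hit]]), positions, d$degenerate_codon)
}

#' Expand a degenerate IUPAC codon
#'
#' Cartesian expansion of a 3-letter IUPAC-ambiguity codon into its concrete
#' DNA codons and their standard-genetic-code translations, retaining codon
#' multiplicity (e.g. `NBT` yields Ser twice, from AGT and TCT).
#'
#' @param codon 3-letter IUPAC string.
#' @return List with `codons` (character vector), `amino_acids` (one-letter
#'   residues, one per codon, named by codon; stops as `*`), and `residues`
#'   (the distinct amino acids, sorted).
#' @export
expand_degenerate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  if (nchar(codon) != 3L) stop("a codon has exactly 3 letters", call. = FALSE)
  letters3 <- strsplit(codon, "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(letters3, names(map))
  if (length(bad)) {
    stop("invalid IUPAC letter '", bad[1], "' in codon ", codon,
         call. = FALSE)
  }
  sets <- lapply(letters3, function(l) strsplit(map[[l]], "")[[1]])
  grid <- expand.grid(b3 = sets[[3]], b2 = sets[[2]], b1 = sets[[1]],
                      stringsAsFactors = FALSE)
  codons <- sort(paste0(grid$b1, grid$b2, grid$b3))
  aas <- Biostrings::GENETIC_CODE[codons]
  names(aas) <- codons
  list(codons = codons, amino_acids = aas,
       residues = sort(unique(unname(aas))))
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons are rendered `*`.
#'
#' @param cds Nucleotide string, length divisible by 3, no ambiguity codes.
#' @return One-letter amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) {
    stop("frame error: sequence length ", nchar(cds),
         " is not divisible by 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", cds)) {
    stop("sequence contains ambiguity codes; clean it first", call. = FALSE)
  }
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Anchor a Sanger read on the template by ungapped alignment
#'
#' Slides the read (and its reverse complement) along the template and keeps
#' the offset with the most matching bases; `N`s count as mismatches. Reads
#' whose best identity falls below `min_identity` — including reads with
#' indels relative to the template, which an ungapped scan cannot place —
#' are rejected as unalignable.
#'
#' @param read Nucleotide string, length 30..template length.
#' @param template Template CDS string.
#' @param min_identity Minimum fraction of matching bases (default 0.7).
#' @return List with `offset` (1-based template position of the read's first
#'   base), `strand` (`"+"`/`"-"`), `matches`, `identity`, and
#'   `oriented_read` (the read in template orientation).
#' @export
align_to_template <- function(read, template, min_identity = 0.7) {
  read <- toupper(as.character(read))
  template <- toupper(as.character(template))
  if (nchar(read) < 30L) {
    stop("read too short to anchor (< 30 nt)", call. = FALSE)
  }
  if (nchar(read) > nchar(template)) {
    stop("read longer than template; not a template substring", call. = FALSE)
  }
  subj <- Biostrings::DNAString(template)
  starts <- seq_len(nchar(template) - nchar(read) + 1L)
  best <- function(r) {
    mism <- Biostrings::neditStartingAt(Biostrings::DNAString(r), subj,
                                        starting.at = starts,
                                        with.indels = FALSE, fixed = TRUE)
    i <- which.min(mism)
    list(offset = starts[i], mismatches = mism[i])
  }
  fwd <- best(read)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read)))
  rev <- best(rc)
  if (fwd$mismatches <= rev$mismatches) {
    hit <- fwd; strand <- "+"; oriented <- read
  } else {
    hit <- rev; strand <- "-"; oriented <- rc
  }
  matches <- nchar(read) - hit$mismatches
  identity <- matches / nchar(read)
  if (identity < min_identity) {
    stop(sprintf("unalignable read: best identity %.2f < %.2f",
                 identity, min_identity), call. = FALSE)
  }
  list(offset = hit$offset, strand = strand, matches = matches,
       identity = identity, oriented_read = oriented)
}

#' Clean a Sanger read against the library design
#'
#' Applies the pipeline's read-cleaning rules, in order: (1) every `N` is
#' replaced by the template base (`N_repair`); (2) every mismatch outside
#' the target codons is reverted to the template base
#' (`off_target_revert`) — such mismatches are sequencing errors by
#' construction of a single-codon library; (3) a target codon whose observed
#' codon is neither in the degenerate expansion nor the template codon is
#' reverted wholesale (`non_degenerate_revert`), never base-by-base, so that
#' cleaning cannot fabricate a degenerate codon that was never sequenced;
#' (4) template positions not covered by the read are filled with template
#' sequence (`short_read_fill`). Target codons touched by N repair or fill
#' are flagged low-confidence.
#'
#' @param read Nucleotide string (any orientation).
#' @param design A [library_design].
#' @param min_identity Passed to [align_to_template()].
#' @param well_id Optional well label carried into the result.
#' @return An object of class `cleaned_read`: list with `well_id`,
#'   `sequence` (template-length cleaned sequence), `edits` (data frame
#'   `position, original, replacement, reason`), `low_confidence_positions`
#'   (amino-acid positions), and the `alignment`.
#' @export
clean_read <- function(read, design, min_identity = 0.7, well_id = NA) {
  stopifnot(inherits(design, "library_design"))
  aln <- align_to_template(read, design$template_cds, min_identity)
  tpl <- strsplit(design$template_cds, "")[[1]]
  n <- length(tpl)
  obs <- strsplit(aln$oriented_read, "")[[1]]
  span <- seq(aln$offset, aln$offset + length(obs) - 1L)

  seqv <- tpl
  seqv[span] <- obs
  covered <- logical(n)
  covered[span] <- TRUE

  target_nt <- as.vector(outer(c(-2L, -1L, 0L), design$target_positions * 3L,
                               `+`))
  in_target <- logical(n)
  in_target[target_nt] <- TRUE

  edits <- list()
  note <- function(pos, orig, repl, reason) {
    if (length(pos) == 0L) return()
    edits[[length(edits) + 1L]] <<- data.frame(
      position = pos, original = orig, replacement = repl, reason = reason,
      stringsAsFactors = FALSE)
  }

  # (1) N repair everywhere
  n_pos <- which(covered & seqv == "N")
  note(n_pos, rep("N", length(n_pos)), tpl[n_pos], "N_repair")
  seqv[n_pos] <- tpl[n_pos]

  # (2) off-target mismatch reversion
  mm <- which(covered & !in_target & seqv != tpl)
  note(mm, seqv[mm], tpl[mm], "off_target_revert")
  seqv[mm] <- tpl[mm]

  # (3) whole-codon reversion of non-degenerate target codons
  low_conf <- integer(0)
  for (p in design$target_positions) {
    idx <- (3L * p - 2L):(3L * p)
    cod <- paste(seqv[idx], collapse = "")
    tcod <- paste(tpl[idx], collapse = "")
    # any residual non-ACGT base fails expansion membership and reverts here
    if (cod != tcod && !(cod %in% design$expansion$codons)) {
      diff <- idx[seqv[idx] != tpl[idx]]
      note(diff, seqv[diff], tpl[diff], "non_degenerate_revert")
      seqv[idx] <- tpl[idx]
    }
    if (any(idx %in% n_pos) || !all(covered[idx])) {
      low_conf <- c(low_conf, p)
    }
  }

  # (4) fill uncovered positions with template
  fill <- which(!covered)
  note(fill, rep("", length(fill)), tpl[fill], "short_read_fill")

  edits <- if (length(edits)) do.call(rbind, edits) else
    data.frame(position = integer(0), original = character(0),
               replacement = character(0), reason = character(0))
  edits <- edits[order(edits$position), , drop = FALSE]
  rownames(edits) <- NULL

  structure(
    list(well_id = well_id, sequence = paste(seqv, collapse = ""),
         edits = edits, low_confidence_positions = sort(unique(low_conf)),
         alignment = aln[c("offset", "strand", "identity")]),
    class = "cleaned_read"
  )
}

#' Call variants from a cleaned read
#'
#' Reports, for every target position of the design, the observed codon and
#' its translation. Codons equal to the template codon are parent calls;
#' codons that differ but translate to the template residue are flagged
#' synonymous. Variant keys use the field's
#' `<template residue><position><observed residue>` convention (e.g.
#' `C335A`).
#'
#' @param cleaned A `cleaned_read` from [clean_read()].
#' @param design The [library_design] used for cleaning.
#' @return Data frame with one row per target position: `well_id, position,
#'   codon, amino_acid, template_codon, template_aa, variant_key, is_parent,
#'   is_synonymous, low_confidence`.
#' @export
call_variant <- function(cleaned, design) {
  stopifnot(inherits(cleaned, "cleaned_read"),
            inherits(design, "library_design"))
  rows <- lapply(design$target_positions, function(p) {
    cod <- substr(cleaned$sequence, 3L * p - 2L, 3L * p)
    tcod <- substr(design$template_cds, 3L * p - 2L, 3L * p)
    aa <- unname(Biostrings::GENETIC_CODE[cod])
    taa <- unname(Biostrings::GENETIC_CODE[tcod])
    data.frame(
      well_id = cleaned$well_id,
      position = p,
      codon = cod,
      amino_acid = aa,
      template_codon = tcod,
      template_aa = taa,
      variant_key = paste0(taa, p, aa),
      is_parent = cod == tcod,
      is_synonymous = cod != tcod && aa == taa,
      low_confidence = p %in% cleaned$low_confidence_positions,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Collapse variant calls to unique variants
#'
#' One row per (position, amino acid) with observation counts summed over
#' wells, ordered by position then residue. Parent calls are dropped by
#' default so the table lists the unique amino-acid variants found in the
#' screen.
#'
#' @param records Data frame of [call_variant()] rows over all wells.
#' @param include_parent Keep rows with `is_parent = TRUE`? Default `FALSE`.
#' @return Data frame `position, amino_acid, variant_key, n_observations`.
#' @export
collapse_unique <- function(records, include_parent = FALSE) {
  if (!include_parent && nrow(records)) {
    records <- records[!records$is_parent, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    return(data.frame(position = integer(0), amino_acid = character(0),
                      variant_key = character(0), n_observations = integer(0)))
  }
  key <- paste(records$position, records$amino_acid)
  agg <- lapply(split(records, key), function(sub) {
    data.frame(position = sub$position[1], amino_acid = sub$amino_acid[1],
               variant_key = sub$variant_key[1], n_observations = nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$position, out$amino_acid), , drop = FALSE]
  rownames(out) <- NULL
  out
}
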