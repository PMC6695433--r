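#' Simulation configuration
#'
#' Parameters of the synthetic front end that stands in for the robotic
#' culture/extraction/GC-MS workflow. Defaults emulate a short fast-GC
#' method: a 0.5-4.6 min acquisition at 0.002 min per scan, narrow Gaussian
#' analyte peaks (sigma 0.012 min), a dominant early-eluting solvent peak
#' that masks co-eluting analytes, a fixed internal-standard spike, and
#' log-normal well-to-well titre variation (sigma 0.3 on the log scale)
#' reflecting growth/induction differences between cultures. Sequencing
#' noise follows a simple Sanger error model: per-base substitutions,
#' per-base N calls, and uniform truncation from either read end.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, inputs, seed).
#' @param rt_min,rt_max,scan_interval Acquisition window and scan spacing,
#'   minutes.
#' @param peak_sigma Gaussian width (sigma, minutes) of analyte peaks.
#' @param solvent_rt,solvent_area,solvent_sigma Retention time, area and
#'   width of the extraction-solvent peak.
#' @param is_area True internal-standard peak area (counts x min).
#' @param titre_noise_sigma Log-normal sigma of the per-well titre factor.
#' @param noise_sd Standard deviation of white baseline noise on the TIC
#'   (counts; default 2, small against apex intensities of 1e4-1e5);
#'   0 for noiseless runs.
#' @param background_area Trace area of each targeted compound present in
#'   every well (solvent bleed/carry-over); 0 disables background.
#' @param read_error_rate Per-base substitution probability.
#' @param n_rate Per-base probability of an N call.
#' @param truncation_max Maximum number of bases clipped (uniformly at
#'   random) from each read end.
#' @param revcomp_prob Probability a read is reported on the reverse strand.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       rt_min = 0.5, rt_max = 4.6, scan_interval = 0.002,
                       peak_sigma = 0.012,
                       solvent_rt = 1.0, solvent_area = 5e5,
                       solvent_sigma = 0.05,
                       is_area = 1e4,
                       titre_noise_sigma = 0.3,
                       noise_sd = 2,
                       background_area = 0,
                       read_error_rate = 0.001,
                       n_rate = 0.002,
                       truncation_max = 30L,
                       revcomp_prob = 0.5) {
  cfg <- list(seed = as.integer(seed), rt_min = rt_min, rt_max = rt_max,
              scan_interval = scan_interval, peak_sigma = peak_sigma,
              solvent_rt = solvent_rt, solvent_area = solvent_area,
              solvent_sigma = solvent_sigma, is_area = is_area,
              titre_noise_sigma = titre_noise_sigma, noise_sd = noise_sd,
              background_area = background_area,
              read_error_rate = read_error_rate, n_rate = n_rate,
              truncation_max = as.integer(truncation_max),
              revcomp_prob = revcomp_prob)
  rates <- c(cfg$read_error_rate, cfg$n_rate, cfg$revcomp_prob)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]",
                                       call. = FALSE)
  if (cfg$peak_sigma <= 0 || cfg$solvent_sigma <= 0 ||
      cfg$scan_interval <= 0) {
    stop("widths and scan interval must be > 0", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Default synthetic compound reference table
#'
#' A synthetic targeted panel modelled on a monoterpene screen: four
#' quantified peaks (alpha-pinene, beta-pinene, limonene, and the merged
#' sabinene/myrcene peak, which co-elute too closely to separate on a fast
#' method), an internal standard (sec-butylbenzene), and two solvent-masked
#' analytes (geraniol, linalool) eluting inside the dodecane solvent window.
#' Retention times and ion ratios are synthetic, chosen to be
#' chromatographically well separated at the default peak width; primary
#' ions follow the compounds' characteristic EI fragments.
#'
#' @return A [compound_refs] table.
#' @export
default_compound_table <- function() {
  compound_refs(
    name = c("sec-butylbenzene", "sabinene/myrcene", "alpha-pinene",
             "beta-pinene", "limonene", "linalool", "geraniol"),
    expected_rt = c(2.00, 2.50, 2.80, 3.20, 3.60, 0.95, 1.05),
    rt_tolerance = 0.05,
    primary_ion = c(105, 93, 93, 93, 68, 71, 69),
    qualifier_ions = list(c(134, 91), c(77, 136), c(91, 136), c(69, 136),
                          c(93, 136), c(93, 55), c(41, 93)),
    solvent_masked = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    is_internal_standard = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

# split one source's TIC contribution over its diagnostic ions
ion_split <- function(primary_ion, qualifier_ions) {
  ions <- c(primary_ion, qualifier_ions)
  w <- c(0.6, 0.25, 0.15)[seq_along(ions)]
  stats::setNames(w / sum(w), ions)
}

#' Simulate one well's chromatogram with planted truth
#'
#' Builds a synthetic GC-MS run: one Gaussian TIC peak per compound with the
#' planted area at the compound's reference retention time, a dominant
#' solvent peak, the internal-standard peak, optional flat background trace
#' and white noise. Per-scan spectra place each source's intensity on its
#' primary and qualifier ions at fixed ratios (0.6 / 0.25 / 0.15) — enough
#' spectral realism to exercise the identification rule, no more.
#'
#' @param true_profile Named vector compound -> planted area (counts x min);
#'   compounds absent from the vector get area 0.
#' @param cfg A [sim_config].
#' @param refs A [compound_refs] table (default [default_compound_table()]).
#' @param well_id Well label.
#' @param seed Optional seed overriding `cfg$seed` (used by plate-level
#'   generators to decorrelate wells).
#' @return List with `chromatogram` and `truth` (list: `well_id`, planted
#'   `areas` incl. internal standard, `is_area`).
#' @export
simulate_chromatogram <- function(true_profile, cfg = sim_config(),
                                  refs = default_compound_table(),
                                  well_id = "A1", seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(refs, "compound_refs"))
  if (any(true_profile < 0)) stop("planted areas must be >= 0",
                                  call. = FALSE)
  set.seed(if (is.null(seed)) cfg$seed else seed)
  rt <- seq(cfg$rt_min, cfg$rt_max, by = cfg$scan_interval)
  n <- length(rt)

  areas <- stats::setNames(rep(0, nrow(refs)), refs$name)
  areas[names(true_profile)] <- true_profile
  if (cfg$background_area > 0) {
    tgt <- targeted_compounds(refs)
    areas[tgt] <- areas[tgt] + cfg$background_area
  }
  is_name <- refs$name[refs$is_internal_standard]
  areas[is_name] <- cfg$is_area

  long <- list()
  add_source <- function(rt0, sigma, area, split) {
    if (area <= 0) return()
    dens <- area * stats::dnorm(rt, rt0, sigma)
    live <- which(dens > 1e-6 * max(dens))
    for (ion in names(split)) {
      long[[length(long) + 1L]] <<- data.frame(
        scan = live, mz = as.numeric(ion),
        intensity = dens[live] * split[[ion]])
    }
  }
  for (i in seq_len(nrow(refs))) {
    add_source(refs$expected_rt[i], cfg$peak_sigma, areas[refs$name[i]],
               ion_split(refs$primary_ion[i], refs$qualifier_ions[[i]]))
  }
  add_source(cfg$solvent_rt, cfg$solvent_sigma, cfg$solvent_area,
             stats::setNames(c(0.7, 0.3), c(57, 43)))

  long <- do.call(rbind, long)
  if (cfg$noise_sd > 0) {
    noise <- pmax(0, stats::rnorm(n, 0, cfg$noise_sd))
    long <- rbind(long, data.frame(scan = seq_len(n), mz = 207,  # column bleed
                                   intensity = noise)[noise > 0, ])
  }
  long <- long[long$intensity > 0, , drop = FALSE]
  spectra <- rep(list(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("mz", "intensity")))), n)
  for (s in split(long, long$scan)) {
    agg <- rowsum(s$intensity, s$mz)  # co-eluting sources share ions
    spectra[[s$scan[1]]] <- cbind(mz = as.numeric(rownames(agg)),
                                  intensity = agg[, 1])
  }
  chrom <- chromatogram(well_id, rt, spectra,
                        metadata = list(simulated = TRUE))
  list(chromatogram = chrom,
       truth = list(well_id = well_id, areas = areas, is_area = cfg$is_area))
}

#' Built-in synthetic variant pool
#'
#' A small panel of planted variant phenotypes used by [simulate_screen()]:
#' the parent enzyme's mixed profile plus codon-labelled variants shifting
#' the product spectrum toward single products, a low-activity variant and
#' an inactive one. Areas are mean planted peak areas (counts x min) before
#' titre noise; codons are members of the NBT expansion.
#'
#' @param parent_codon Template codon at the randomized position (used for
#'   labelling only; parent wells keep the template sequence).
#' @return Data frame `label, codon, prob` with a list-column `profile` of
#'   named area vectors.
#' @export
default_variant_pool <- function(parent_codon = "TGT") {
  profiles <- list(
    parent_like = c("alpha-pinene" = 3000, "beta-pinene" = 2500,
                    "limonene" = 2800, "sabinene/myrcene" = 2600),
    high_pinene = c("alpha-pinene" = 9000, "beta-pinene" = 1200,
                    "limonene" = 400, "sabinene/myrcene" = 300),
    limonene_shift = c("alpha-pinene" = 500, "beta-pinene" = 300,
                       "limonene" = 7000, "sabinene/myrcene" = 900),
    low_activity = c("alpha-pinene" = 600, "beta-pinene" = 500,
                     "limonene" = 560, "sabinene/myrcene" = 520),
    inactive = c("alpha-pinene" = 0, "beta-pinene" = 0,
                 "limonene" = 0, "sabinene/myrcene" = 0)
  )
  pool <- data.frame(
    label = names(profiles),
    codon = c("GCT", "GGT", "CTT", "ACT", "CGT"),
    prob = c(0.25, 0.2, 0.2, 0.15, 0.2),
    stringsAsFactors = FALSE
  )
  pool$profile <- unname(profiles)
  attr(pool, "parent_profile") <- profiles$parent_like
  attr(pool, "parent_codon") <- parent_codon
  pool
}

#' Simulate a random single-position library design
#'
#' Generates a random template CDS (ATG start, no in-frame stops, stop
#' codon at the end) and places the degenerate codon design on it.
#'
#' @param n_codons Template length in codons (incl. start and stop).
#' @param positions Target amino-acid positions (default: one position near
#'   the middle).
#' @param degenerate_codon IUPAC codon, default `"NBT"`.
#' @param seed Integer seed.
#' @return A [library_design].
#' @export
simulate_library_design <- function(n_codons = 200, positions = NULL,
                                    degenerate_codon = "NBT", seed = 1L) {
  set.seed(seed)
  stopifnot(n_codons >= 10)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(which(Biostrings::GENETIC_CODE == "*")))
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  template <- paste0("ATG", paste(body, collapse = ""), "TAA")
  if (is.null(positions)) positions <- ceiling(n_codons / 2)
  library_design(template, positions, degenerate_codon)
}

well_grid_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Simulate a full screening plate with planted truth
#'
#' Lays out one 96-well plate (parent controls first, then solvent-only
#' controls, then library sample wells), draws a planted variant for every
#' sample well from the variant pool, applies log-normal titre noise, and
#' generates the chromatogram of every well plus a Sanger read for every
#' sample well. The truth record carries, per well, the planted variant,
#' codon, realized areas, the planted active state, and the planted fold
#' change of each compound over the parent wells' realized median — all the
#' information needed to score every downstream stage.
#'
#' @param design A [library_design] (single target position used for reads).
#' @param pool Variant pool data frame (see [default_variant_pool()]).
#' @param wells_per_library Number of library sample wells (default 40, the
#'   per-library screening depth that puts per-codon coverage above 0.95
#'   for a 12-codon library).
#' @param n_parent,n_solvent Control wells per plate (defaults 8 and 4).
#' @param cfg A [sim_config]; `cfg$seed` seeds the whole plate.
#' @param refs Compound reference table.
#' @param plate_id Plate label.
#' @return List with `layout`, `chromatograms` (named list), `reads` (named
#'   character vector, sample wells), `truth` (list: `wells` data frame,
#'   `fold_changes` data frame, `parent_profile`), `design`, `refs`, `cfg`.
#' @export
simulate_screen <- function(design, pool = default_variant_pool(),
                            wells_per_library = 40, n_parent = 8,
                            n_solvent = 4, cfg = sim_config(),
                            refs = default_compound_table(),
                            plate_id = "P1") {
  stopifnot(wells_per_library >= 1, n_parent >= 1, n_solvent >= 1)
  n_wells <- n_parent + n_solvent + wells_per_library
  grid <- well_grid_96()
  if (n_wells > length(grid)) stop("more than 96 wells requested",
                                   call. = FALSE)
  set.seed(cfg$seed)
  wells <- grid[seq_len(n_wells)]
  roles <- c(rep("parent_control", n_parent), rep("solvent_control", n_solvent),
             rep("sample", wells_per_library))
  layout <- data.frame(
    plate_id = plate_id, well_id = wells, role = roles,
    library_id = ifelse(roles == "sample", "LIB1", roles),
    stringsAsFactors = FALSE
  )
  parent_profile <- attr(pool, "parent_profile")
  tgt <- targeted_compounds(refs)

  draw <- sample(seq_len(nrow(pool)), wells_per_library, replace = TRUE,
                 prob = pool$prob)
  titre <- stats::rlnorm(n_wells, 0, cfg$titre_noise_sigma)
  well_seed <- sample.int(.Machine$integer.max, n_wells)

  profiles <- vector("list", n_wells)
  labels <- codons <- character(n_wells)
  for (i in seq_len(n_wells)) {
    if (roles[i] == "parent_control") {
      profiles[[i]] <- parent_profile * titre[i]
      labels[i] <- "parent"
      codons[i] <- attr(pool, "parent_codon")
    } else if (roles[i] == "solvent_control") {
      profiles[[i]] <- stats::setNames(numeric(0), character(0))
      titre[i] <- NA_real_
      labels[i] <- "solvent"
      codons[i] <- NA_character_
    } else {
      k <- draw[i - n_parent - n_solvent]
      profiles[[i]] <- pool$profile[[k]] * titre[i]
      labels[i] <- pool$label[k]
      codons[i] <- pool$codon[k]
    }
  }
  chroms <- lapply(seq_len(n_wells), function(i) {
    simulate_chromatogram(profiles[[i]], cfg, refs, well_id = wells[i],
                          seed = well_seed[i])$chromatogram
  })
  names(chroms) <- wells

  area_mat <- t(vapply(profiles, function(p) {
    v <- stats::setNames(rep(0, length(tgt)), tgt)
    v[intersect(names(p), tgt)] <- p[intersect(names(p), tgt)]
    v
  }, numeric(length(tgt))))
  norm_mat <- area_mat / cfg$is_area
  parent_median <- apply(norm_mat[roles == "parent_control", , drop = FALSE],
                         2, stats::median)

  truth_wells <- data.frame(
    well_id = wells, role = roles, variant = labels, codon = codons,
    titre_factor = titre,
    active = roles == "sample" & rowSums(area_mat) > 0,
    stringsAsFactors = FALSE
  )
  truth_wells <- cbind(truth_wells,
                       stats::setNames(as.data.frame(norm_mat),
                                       paste0("norm.", tgt)))
  fc_rows <- lapply(which(roles == "sample"), function(i) {
    fc <- ifelse(parent_median > 0, norm_mat[i, ] / parent_median,
                 ifelse(norm_mat[i, ] > 0, Inf, 1))
    data.frame(well_id = wells[i], compound = tgt, fold_change = unname(fc),
               stringsAsFactors = FALSE)
  })
  truth_fc <- do.call(rbind, fc_rows)

  sample_idx <- which(roles == "sample")
  assignments <- data.frame(
    well_id = wells[sample_idx],
    position = design$target_positions[1],
    codon = codons[sample_idx],
    stringsAsFactors = FALSE
  )
  reads <- simulate_reads(design, assignments, cfg,
                          seed = well_seed[1] %% .Machine$integer.max)$reads

  list(layout = layout, chromatograms = chroms, reads = reads,
       truth = list(wells = truth_wells, fold_changes = truth_fc,
                    parent_profile = relative_profile(parent_profile)),
       design = design, refs = refs, cfg = cfg)
}

#' Simulate Sanger reads for assigned variant codons
#'
#' Each read is the template with the planted codon substituted at its
#' target position, then truncated uniformly at random from both ends (up
#' to `cfg$truncation_max` bases), hit by per-base substitution errors and
#' N calls, and reverse-complemented with probability `cfg$revcomp_prob`.
#'
#' @param design A [library_design].
#' @param assignments Data frame `well_id, position, codon`; codons must be
#'   the template codon or members of the degenerate expansion.
#' @param cfg A [sim_config].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return List with `reads` (named character vector, names = well ids) and
#'   `truth` (the assignments plus per-read strand and clip columns).
#' @export
simulate_reads <- function(design, assignments, cfg = sim_config(),
                           seed = NULL) {
  stopifnot(inherits(design, "library_design"))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  bases <- c("A", "C", "G", "T")
  tpl <- strsplit(design$template_cds, "")[[1]]
  truth <- assignments
  truth$strand <- NA_character_
  truth$clip_start <- truth$clip_end <- NA_integer_
  reads <- character(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    p <- assignments$position[i]
    cod <- assignments$codon[i]
    tcod <- substr(design$template_cds, 3 * p - 2, 3 * p)
    if (!(p %in% design$target_positions)) {
      stop("position ", p, " is not a target position", call. = FALSE)
    }
    if (!(cod %in% c(design$expansion$codons, tcod))) {
      stop("codon ", cod, " at position ", p,
           " is neither the template codon nor in the ",
           design$degenerate_codon, " expansion", call. = FALSE)
    }
    v <- tpl
    v[(3 * p - 2):(3 * p)] <- strsplit(cod, "")[[1]]
    cs <- sample.int(cfg$truncation_max + 1L, 1L) - 1L
    ce <- sample.int(cfg$truncation_max + 1L, 1L) - 1L
    v <- v[(1 + cs):(length(v) - ce)]
    err <- stats::runif(length(v)) < cfg$read_error_rate
    if (any(err)) {
      v[err] <- vapply(v[err],
                       function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    }
    nn <- stats::runif(length(v)) < cfg$n_rate
    v[nn] <- "N"
    s <- paste(v, collapse = "")
    strand <- "+"
    if (stats::runif(1) < cfg$revcomp_prob) {
      s <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      strand <- "-"
    }
    reads[i] <- s
    truth$strand[i] <- strand
    truth$clip_start[i] <- cs
    truth$clip_end[i] <- ce
  }
  names(reads) <- assignments$well_id
  list(reads = reads, truth = truth)
}

#' Write a simulated screen to a directory
#'
#' Serializes a [simulate_screen()] result as plain files: `layout.csv`,
#' one scan-table TSV per well under `wells/`, `reads.fasta`, and
#' `truth.json` (requires \pkg{jsonlite}).
#'
#' @param sim A [simulate_screen()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_dir <- function(sim, dir) {
  dir.create(file.path(dir, "wells"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$layout, file.path(dir, "layout.csv"),
                   row.names = FALSE)
  for (w in names(sim$chromatograms)) {
    write_chrom_table(sim$chromatograms[[w]],
                      file.path(dir, "wells", paste0(w, ".tsv")))
  }
  dna <- Biostrings::DNAStringSet(sim$reads)
  Biostrings::writeXStringSet(dna, file.path(dir, "reads.fasta"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
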