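# Independent oracles, deliberately implemented apart from the package code.

# Standard genetic code from the classic compact encoding (base order TCAG),
# a second implementation independent of Biostrings' GENETIC_CODE.
oracle_code_table <- local({
  b <- c("T", "C", "A", "G")
  # codons vary fastest in base 3, then base 2, then base 1
  codons <- unlist(lapply(b, function(b1)
    unlist(lapply(b, function(b2) paste0(b1, b2, b)))))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(oracle_code_table[codons], collapse = "")
}

# brute-force degenerate codon expansion from hand-written IUPAC sets
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_expand <- function(codon) {
  l <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (b1 in oracle_iupac[[l[1]]])
    for (b2 in oracle_iupac[[l[2]]])
      for (b3 in oracle_iupac[[l[3]]])
        out <- c(out, paste0(b1, b2, b3))
  sort(out)
}

# analytic Gaussian curve for planting chromatographic peaks
gaussian_curve <- function(rt, rt0, sigma, area) {
  area * exp(-(rt - rt0)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

# sort-based quantile oracle (linear interpolation, as quantile type 7)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# minimal mzXML writer (32-bit network-order base64 peak blocks) used only
# to build fixtures for the reader
write_fixture_mzxml <- function(chrom, path) {
  enc <- function(mz, int) {
    v <- as.numeric(rbind(mz, int))
    jsonlite::base64_enc(writeBin(v, raw(), size = 4, endian = "big"))
  }
  scans <- vapply(seq_along(chrom$rt), function(i) {
    s <- chrom$spectra[[i]]
    sprintf(paste0(
      '<scan num="%d" msLevel="1" peaksCount="%d" retentionTime="PT%.6fS">\n',
      '<peaks precision="32" byteOrder="network" contentType="m/z-int" ',
      'compressionType="none" compressedLen="0">%s</peaks>\n</scan>'),
      i, nrow(s), chrom$rt[i] * 60, enc(s[, "mz"], s[, "intensity"]))
  }, character(1))
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">\n',
    '<msRun scanCount="%d">\n%s\n</msRun>\n</mzXML>'),
    length(chrom$rt), paste(scans, collapse = "\n"))
  writeLines(doc, path)
  invisible(path)
}

# small in-memory chromatogram shared by reader tests
make_tiny_chrom <- function() {
  chromatogram(
    "A1",
    rt = c(1.00, 1.01, 1.02),
    spectra = list(
      cbind(mz = c(93, 136), intensity = c(100, 50)),
      cbind(mz = 93, intensity = 500),
      cbind(mz = c(68, 93), intensity = c(30, 80))
    )
  )
}

# reference table with a single analyte + internal standard, no masking
two_compound_refs <- function() {
  compound_refs(
    name = c("IS", "pinene"),
    expected_rt = c(1.0, 2.0),
    rt_tolerance = 0.05,
    primary_ion = c(105, 93),
    qualifier_ions = list(134, c(91, 136)),
    is_internal_standard = c(TRUE, FALSE)
  )
}

# build a chromatogram from planted Gaussian TIC peaks; each peak carries a
# single diagnostic ion so identification can run on it
planted_chrom <- function(peaks, rt = seq(0.5, 4.6, by = 0.002),
                          well_id = "W1") {
  tic <- rep(0, length(rt))
  per_peak <- lapply(seq_len(nrow(peaks)), function(i) {
    gaussian_curve(rt, peaks$rt[i], peaks$sigma[i], peaks$area[i])
  })
  spectra <- lapply(seq_along(rt), function(j) {
    mzs <- ints <- numeric(0)
    for (i in seq_len(nrow(peaks))) {
      v <- per_peak[[i]][j]
      if (v > 1e-9) {
        mzs <- c(mzs, peaks$ion[i])
        ints <- c(ints, v)
      }
    }
    cbind(mz = mzs, intensity = ints)
  })
  chromatogram(well_id, rt, spectra)
}

# bare-bones well result for screen-level tests that need no chromatography
fake_well <- function(well_id, norm, role = "sample", masked = NULL) {
  cpds <- names(norm)
  masked_flag <- cpds %in% (masked %||% character(0))
  norm[masked_flag] <- NA_real_
  res <- list(
    well_id = well_id, role = role, status = "ok", is_area = 1,
    normalized_area = norm, area = norm,
    flags = data.frame(compound = cpds, is_masked = masked_flag,
                       is_missing = !masked_flag & norm == 0,
                       below_threshold = NA, stringsAsFactors = FALSE)
  )
  class(res) <- "well_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
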