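test_that("scan-table and mzXML readers agree on the same run", {
  chrom <- make_tiny_chrom()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  xml <- withr::local_tempfile(fileext = ".mzXML")
  write_chrom_table(chrom, tsv)
  write_fixture_mzxml(chrom, xml)

  from_tsv <- read_mzxml(tsv, well_id = "A1")
  from_xml <- read_mzxml(xml, well_id = "A1")

  expect_equal(from_tsv$rt, chrom$rt)
  expect_equal(from_tsv$spectra, chrom$spectra, ignore_attr = TRUE)
  # mzXML stores 32-bit floats: equal within single precision
  expect_equal(from_xml$rt, chrom$rt, tolerance = 1e-6)
  for (i in seq_along(chrom$spectra)) {
    expect_equal(from_xml$spectra[[i]], chrom$spectra[[i]],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("reader enforces ordering and rejects empty or broken input", {
  expect_error(read_mzxml(tempfile(fileext = ".tsv")), "no such file")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("scan_time_min\tmz\tintensity", empty)
  expect_error(read_chrom_table(empty), "empty run")

  bad <- withr::local_tempfile(fileext = ".mzXML")
  writeLines("<mzXML><msRun><scan truncated", bad)
  expect_error(read_mzxml(bad), "parse")

  expect_warning(
    chromatogram("A1", c(1.02, 1.00, 1.01),
                 rep(list(cbind(mz = 93, intensity = 1)), 3)),
    "re-sorting"
  )
  out <- suppressWarnings(
    chromatogram("A1", c(1.02, 1.00, 1.01),
                 rep(list(cbind(mz = 93, intensity = 1)), 3)))
  expect_true(!is.unsorted(out$rt, strictly = TRUE))
  expect_error(chromatogram("A1", 1.0, list(cbind(mz = 93, intensity = 1))),
               "at least 2 scans")
})

test_that("TIC equals the per-scan brute-force sum and ignores mz order", {
  chrom <- make_tiny_chrom()
  tic <- total_ion_chromatogram(chrom)
  expect_equal(tic$intensity, c(150, 500, 110))

  set.seed(42)
  spectra <- lapply(1:20, function(i) {
    k <- sample(0:6, 1)
    cbind(mz = sample(50:250, k), intensity = stats::runif(k, 0, 1e4))
  })
  chrom2 <- chromatogram("B2", seq(1, by = 0.01, length.out = 20), spectra)
  tic2 <- total_ion_chromatogram(chrom2)
  brute <- vapply(spectra, function(s) sum(s[, 2]), numeric(1))
  expect_equal(tic2$intensity, brute)

  shuffled <- lapply(spectra, function(s) s[sample(nrow(s)), , drop = FALSE])
  chrom3 <- chromatogram("B3", chrom2$rt, shuffled)
  expect_equal(total_ion_chromatogram(chrom3)$intensity, tic2$intensity)

  zero <- chromatogram("Z", c(1, 2), rep(list(cbind(mz = numeric(0),
                                                    intensity = numeric(0))),
                                         2))
  expect_equal(total_ion_chromatogram(zero)$intensity, c(0, 0))
})

test_that("peak picking finds planted Gaussians with valley bounds", {
  rt <- seq(0, 4, by = 0.005)
  one <- data.frame(rt = rt, intensity = gaussian_curve(rt, 2, 0.02, 1000))
  pk <- pick_peaks(one, min_prominence = 100)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$apex_rt - 2), 0.005 + 1e-12)

  flat <- data.frame(rt = rt, intensity = rep(0, length(rt)))
  expect_equal(nrow(pick_peaks(flat)), 0L)
  expect_error(pick_peaks(flat[1:2, ]), "at least 3 scans")

  # two Gaussians > 4 sigma apart: valley between them found by brute force
  sig <- 0.05
  y <- gaussian_curve(rt, 1.5, sig, 800) + gaussian_curve(rt, 1.9, sig, 400)
  two <- data.frame(rt = rt, intensity = y)
  pk2 <- pick_peaks(two, min_prominence = 10)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$apex_rt, sort(pk2$apex_rt))
  between <- rt > 1.5 & rt < 1.9
  valley_rt <- rt[between][which.min(y[between])]
  expect_equal(pk2$right_rt[1], valley_rt, tolerance = 1e-9)
  expect_equal(pk2$left_rt[2], valley_rt, tolerance = 1e-9)
})

test_that("prominence and width filters drop noise ripples", {
  rt <- seq(0, 2, by = 0.005)
  y <- gaussian_curve(rt, 1, 0.03, 500)
  set.seed(7)
  y <- y + stats::runif(length(y), 0, 5)
  pk <- pick_peaks(data.frame(rt = rt, intensity = y),
                   min_prominence = 200, min_width_scans = 5)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$apex_rt - 1), 0.01)
})

test_that("identification matches RT window plus dominant primary ion", {
  refs <- two_compound_refs()
  peaks <- data.frame(
    apex_idx = c(1L, 2L), apex_rt = c(1.0, 2.01), left_rt = c(0.9, 1.9),
    right_rt = c(1.1, 2.1), apex_intensity = c(100, 100),
    prominence = c(100, 100), area = c(10, 20),
    compound = NA_character_, stringsAsFactors = FALSE
  )
  chrom <- chromatogram("X", c(1.0, 2.01),
                        list(cbind(mz = c(105, 134), intensity = c(90, 30)),
                             cbind(mz = c(93, 136), intensity = c(80, 20))))
  out <- identify_peaks(peaks, chrom, refs)
  expect_equal(out$compound, c("IS", "pinene"))

  # far outside every window: unassigned
  far <- peaks
  far$apex_rt <- c(1.2, 2.2)
  expect_true(all(is.na(identify_peaks(far, chrom, refs)$compound)))

  # qualifier ion dominating the apex spectrum vetoes the assignment
  chrom_bad <- chromatogram("X", c(1.0, 2.01),
                            list(cbind(mz = c(105, 134),
                                       intensity = c(90, 30)),
                                 cbind(mz = c(93, 136),
                                       intensity = c(20, 80))))
  out_bad <- identify_peaks(peaks, chrom_bad, refs)
  expect_true(is.na(out_bad$compound[2]))
})

test_that("closest peak wins when several fall in one RT window", {
  refs <- two_compound_refs()
  peaks <- data.frame(
    apex_idx = 1:3, apex_rt = c(1.0, 1.98, 2.01), left_rt = c(0.9, 1.9, 2.0),
    right_rt = c(1.1, 2.0, 2.1), apex_intensity = 100, prominence = 100,
    area = c(10, 5, 20), compound = NA_character_, stringsAsFactors = FALSE
  )
  spec_is <- cbind(mz = c(105, 134), intensity = c(90, 30))
  spec_pin <- cbind(mz = c(93, 136), intensity = c(80, 20))
  chrom <- chromatogram("X", c(1.0, 1.98, 2.01),
                        list(spec_is, spec_pin, spec_pin))
  out <- identify_peaks(peaks, chrom, refs)
  # oracle: peak 3 is nearer to 2.0 than peak 2
  drt <- abs(peaks$apex_rt[2:3] - 2.0)
  expect_equal(which.min(drt), 2L)
  expect_true(is.na(out$compound[2]))
  expect_equal(out$compound[3], "pinene")
  # partial matching: assigned compounds and peaks are both unique
  expect_false(anyDuplicated(stats::na.omit(out$compound)) > 0)
})

test_that("solvent-masked compounds are never assigned", {
  refs <- compound_refs(
    name = c("IS", "geraniol"), expected_rt = c(1.0, 2.0),
    primary_ion = c(105, 69), qualifier_ions = list(134, 41),
    solvent_masked = c(FALSE, TRUE),
    is_internal_standard = c(TRUE, FALSE)
  )
  peaks <- data.frame(
    apex_idx = c(1L, 2L), apex_rt = c(1.0, 2.0), left_rt = c(0.9, 1.9),
    right_rt = c(1.1, 2.1), apex_intensity = 100, prominence = 100,
    area = c(10, 20), compound = NA_character_, stringsAsFactors = FALSE
  )
  chrom <- chromatogram("X", c(1.0, 2.0),
                        list(cbind(mz = c(105, 134), intensity = c(90, 30)),
                             cbind(mz = c(69, 41), intensity = c(90, 30))))
  out <- identify_peaks(peaks, chrom, refs)
  expect_true(is.na(out$compound[2]))
  w <- normalize_well(out, refs, "X")
  expect_true(w$flags$is_masked[w$flags$compound == "geraniol"])
  expect_true(is.na(w$normalized_area[["geraniol"]]))
})

test_that("normalization divides by the internal standard and flags gaps", {
  refs <- two_compound_refs()
  peaks <- data.frame(
    apex_idx = c(1L, 2L), apex_rt = c(1.0, 2.0), left_rt = c(0.9, 1.9),
    right_rt = c(1.1, 2.1), apex_intensity = 100, prominence = 100,
    area = c(1000, 500), compound = c("IS", "pinene"),
    stringsAsFactors = FALSE
  )
  w <- normalize_well(peaks, refs, "A1")
  expect_equal(w$normalized_area[["pinene"]], 0.5)
  expect_equal(w$status, "ok")

  only_is <- peaks[1, , drop = FALSE]
  w2 <- normalize_well(only_is, refs, "A2")
  expect_equal(w2$normalized_area[["pinene"]], 0)
  expect_true(w2$flags$is_missing[w2$flags$compound == "pinene"])

  no_is <- peaks[2, , drop = FALSE]
  w3 <- normalize_well(no_is, refs, "A3")
  expect_equal(w3$status, "failed")
  expect_true(all(is.na(w3$normalized_area)))
})

test_that("trapezoidal integration recovers a triangular peak's analytic area", {
  # triangle of height h over width w has area h*w/2
  h <- 600
  w <- 0.2
  rt <- seq(0.5, 1.5, by = 0.001)
  y <- pmax(0, h * (1 - abs(rt - 1) / (w / 2)))
  pk <- pick_peaks(data.frame(rt = rt, intensity = y), min_prominence = 10)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$area - h * w / 2) / (h * w / 2), 0.01)
})

test_that("normalized areas are invariant under uniform intensity scaling", {
  refs <- two_compound_refs()
  base <- planted_chrom(data.frame(rt = c(1.0, 2.0), sigma = 0.02,
                                   area = c(1000, 400), ion = c(105, 93)))
  scaled <- chromatogram(base$well_id, base$rt,
                         lapply(base$spectra, function(s) {
                           s[, "intensity"] <- s[, "intensity"] * 7.3
                           s
                         }))
  w1 <- process_well(base, refs)
  w2 <- process_well(scaled, refs, min_prominence = 100 * 7.3)
  expect_equal(w1$normalized_area, w2$normalized_area, tolerance = 1e-9)
})

test_that("thresholds are the arithmetic mean over solvent-only wells", {
  cpds <- c(a = 0.01, b = 0)
  w1 <- fake_well("S1", c(a = 0.01, b = 0), role = "solvent_control")
  w2 <- fake_well("S2", c(a = 0.03, b = 0), role = "solvent_control")
  thr <- compute_thresholds(list(w1, w2))
  expect_equal(unname(thr["a"]), 0.02)
  expect_equal(unname(thr["b"]), 0)
  expect_error(compute_thresholds(list()), "no usable solvent-control")

  # 8 simulated solvent wells with known draws: independent mean oracle
  set.seed(11)
  draws <- stats::runif(8, 0, 0.05)
  wells <- lapply(seq_along(draws), function(i)
    fake_well(paste0("S", i), c(a = draws[i], b = 0),
              role = "solvent_control"))
  thr8 <- compute_thresholds(wells)
  expect_equal(unname(thr8["a"]), sum(draws) / 8)
})
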