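Package: terpscreen
Title: Automated Screening Analytics for Monoterpene Synthase Variant Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Plate-based screening analytics for degenerate-codon libraries of
    monoterpene cyclase/synthase enzymes assayed in vivo by targeted GC-MS.
    Reads per-well chromatograms (mzXML or a plain scan-table dialect), picks
    and identifies peaks on the total ion chromatogram, integrates and
    normalizes them to an internal standard, and calls active variants against
    solvent-only background thresholds. Cleans Sanger reads against a template
    coding sequence under a degenerate-codon library design, validates and
    translates variant codons, and scores sequence-function relationships:
    relative product profiles, Euclidean distance to the parent profile,
    per-position amino-acid plasticity, occurrence tables and library coverage
    probabilities. A synthetic-data generator with planted ground truth stands
    in for the robotic and wet-lab front end so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    mzR,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
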