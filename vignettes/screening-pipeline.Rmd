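---
title: "Methods: plate-based screening analytics for monoterpene synthase libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate-based screening analytics for monoterpene synthase libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terpscreen)
```

`terpscreen` covers the computational side of an in vivo screen of
monoterpene cyclase/synthase (mTC/S) variant libraries: 96-well plates of
*E. coli* cultures expressing enzyme variants, a two-phase organic overlay
(dodecane) capturing the volatile products, targeted GC-MS on each well,
and plate-format Sanger sequencing of the hits. This vignette documents the
models and conventions the package implements, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable convention exists.

## Targeted quantification model

Each well yields one chromatogram; quantification is *targeted*: we ask how
much of each compound in a small reference panel is present, nothing more.
The chain is:

1. **TIC.** All spectral intensities in a scan are summed to a total ion
   count. Working at the TIC level is appropriate because the panel's peaks
   are chromatographically resolved by construction of the GC method; no
   deconvolution is attempted.
2. **Peak picking.** Local maxima on the TIC, kept when their topographic
   prominence is at least `min_prominence` (counts) and their
   valley-to-valley span is at least `min_width_scans` scans. Integration
   bounds are the nearest flanking local minima. This is the simplest
   reproducible operator consistent with targeted extraction; its two knobs
   trade sensitivity against noise ripples and should sit well above the
   baseline noise amplitude (defaults: 100 counts, 3 scans).
3. **Identification.** A peak matches a compound when its apex retention
   time lies within `rt_tolerance` of the compound's expected RT *and* the
   most intense ion at the apex scan, among the compound's primary +
   qualifier ions (m/z matched within `mz_tol = 0.3`), is the primary ion.
   Qualifier-ion *ratios* are not checked — only dominance of the primary
   ion. Assignment is a globally greedy partial matching by increasing
   |ΔRT| (ties by reference-table order), so each compound gets at most one
   peak and vice versa. The default `rt_tolerance` of 0.05 min suits a
   short (≈ 4.6 min) fast-GC method and must be retuned per instrument.
4. **Integration and normalization.** Trapezoidal rule on the TIC between
   the valley bounds; each compound's area is divided by the
   internal-standard (sec-butylbenzene) area of the same well, cancelling
   injection-volume and extraction variability. A well without a usable
   internal-standard peak is *failed* and excluded everywhere downstream —
   never imputed.
5. **Masking.** Analytes co-eluting with the solvent peak (e.g. geraniol,
   linalool under dodecane) are flagged `is_masked`, reported `NA`, and
   excluded from thresholds, active calls and fold changes. Masking is a
   property of the reference table, not detected from the data.

Two conventions worth stating: all retention times are minutes throughout
(mzXML stores seconds; the reader converts), and areas are counts·min. No
absolute calibration to concentrations is attempted — every downstream
quantity is a ratio.

## Active calls and fold change

The background threshold of a compound is the **arithmetic mean** of its
normalized area over the plate's solvent-only control wells, computed per
plate (controls are on every plate precisely because conditions drift
between plates). A well is **active** when at least one non-masked targeted
compound is **strictly** above its threshold.

Fold change divides a well's normalized area by the **median** over the
plate's parent-control wells. Cross-plate pooling of parent wells is
deliberately not offered: growth and induction conditions vary from plate
to plate, and the within-plate median absorbs exactly that variation. Two
degenerate cases carry flags instead of silent numbers: parent median 0
with positive sample → `Inf` (`parent_zero`); both 0 → 1 by convention
(`both_zero`). Library summaries use linear-interpolation quantiles
(`quantile` type 7, fixed and documented because several conventions
exist); infinite fold changes are excluded from quantiles and counted
separately.

An open choice was whether thresholds apply to raw or normalized areas; we
use normalized areas so thresholds are comparable across wells within a
plate despite injection variability.

## Read cleaning and variant validation

A library design is a template CDS plus target amino-acid positions and one
degenerate codon (default NBT: 12 codons, 11 residues — polar/hydrophobic,
no charged residues except Arg). Reads are anchored on the template by
ungapped sliding alignment over both strands (mismatch counting via
`Biostrings::neditStartingAt`); a read whose best identity is below 70% —
including any read with indels, which an ungapped scan cannot place — is
rejected as unalignable rather than guessed at.

Cleaning applies four rules in a fixed order, every edit logged:

1. `N_repair` — each N becomes the template base;
2. `off_target_revert` — each mismatch outside target codons reverts to
   template (in a single-codon library such mismatches are sequencing
   errors by construction);
3. `non_degenerate_revert` — a target codon that is neither the template
   codon nor in the degenerate expansion reverts **as a whole codon**.
   Per-base repair could manufacture a degenerate codon that was never
   sequenced; whole-codon reversion cannot, at the cost of discarding a
   partially corrupted genuine variant (which then surfaces as a parent
   call);
4. `short_read_fill` — uncovered template positions are filled with
   template sequence.

Rule 4 silently converts non-coverage into parent calls, so any target
codon that was filled or N-repaired is additionally flagged
`low_confidence`; consumers can drop or down-weight those calls. Cleaning
is idempotent, and a cleaned sequence differs from the template only at
target codons and only by expansion members — both properties are enforced
by tests.

Synonymous codon observations at target positions (codon differs,
residue does not) are retained and flagged, never merged into the parent.

## Sequence–function scores

**Relative profiles.** A variant's product profile is its per-compound
amounts normalized to fractions summing to 1. An all-zero titre vector has
no profile — the variant is inactive — rather than a zero vector.

**Euclidean distance.** d(p, q) = √Σ(p_c − q_c)² over the union of both
profiles' compounds, a compound absent from one side contributing its full
fraction from the other. Distances are computed on fractions, not absolute
titres, because a distance of zero must mean "same product distribution"
regardless of expression level; fractions also make the score invariant to
uniform titre scaling. Reports round to 3 decimals; full precision is kept
internally.

**Plasticity score.** For a position with K residues encodable by the
degenerate codon (K = 11 for NBT), let f be the frequency distribution of
the observed **non-parent** residues over that K-residue support. The score
is the histogram intersection with the uniform distribution,
Σ_a min(f_a, 1/K): 0 when no mutations were observed, 1 when all K residues
appear equally often. Excluding parent-residue observations is an
interpretive choice: the intersection of a distribution that includes the
parent can never reach 0, so only the mutant-only convention reproduces
both defining endpoints. Observed residues outside the support (impossible
for validated reads) are rejected at construction.

**Coverage.** With K equiprobable codons and n colonies, the probability a
given codon is seen is 1 − ((K−1)/K)^n — 0.9692 at n = 40, K = 12, hence
the usual "screen ≥ 40 colonies per single-position NBT library" rule —
and the probability all K are seen follows by inclusion–exclusion,
Σ_j (−1)^j C(K,j)((K−j)/K)^n. Codon equiprobability is an idealization of
primer synthesis.

## What the simulator emulates — and what it does not

The generator produces, from a seed and a `sim_config`, byte-identical
chromatograms, plates and reads with planted truth records sufficient to
score every pipeline stage.

Emulated: Gaussian TIC peaks with planted areas at the panel's retention
times; a dominant early solvent peak (area 5·10⁵, σ 0.05 min) that masks
co-eluting analytes; a fixed internal-standard spike (area 10⁴); white
baseline noise (sd 2 counts by default — small against apex intensities of
10⁴–10⁵, as in a healthy targeted method); log-normal well-to-well titre
factors (σ 0.3 on the log scale, emulating growth/induction variability);
per-scan spectra that put each source's intensity on its primary and two
qualifier ions at fixed ratios 0.6/0.25/0.15; Sanger reads as template
substrings with the planted codon, uniform end-truncation (≤ 30 nt per
end), per-base substitutions (0.1%) and N calls (0.2%), and random strand.

Not emulated: real EI fragmentation (spectra carry just enough structure to
exercise the primary-ion rule), peak tailing and RT drift, co-elution
*between targeted analytes*, carry-over, chimeric or indel-bearing reads,
and base-caller quality scores. Passing round trips therefore demonstrate
the pipeline's correctness under resolved-peak, substitution-only
conditions — they do not certify performance on instruments with drifting
RTs or on reads with indels (the latter are deliberately rejected).

One generator default deserves its rationale: the optional solvent-bleed
trace of targeted compounds (`background_area`) defaults to 0, so planted
inactive wells yield no detected signal and thresholds are exercised at
their boundary (all-zero backgrounds give zero thresholds, and "strictly
above" keeps zero-signal wells inactive). A constant trace present equally
in every well would place inactive wells *exactly at* the mean-background
threshold, where the call degenerates to the sign of numerical noise — a
realistic source of the false positives screens do see, but not a sensible
default for a generator whose purpose is planted-truth scoring. Tests
exercise positive backgrounds through the config knob instead.

## Problem sizes and numerical choices

The shipped round trips use: plates of 52–96 wells (40 library wells, 8
parent and 4 solvent controls) on a 0.5–4.6 min RT grid at 0.002 min/scan;
a 200-codon synthetic template with one NBT position; 1000 reads for the
sequence round trip and 10⁵ replicates for the Monte-Carlo coverage check.
These sizes give each estimate comfortable statistical resolution while
keeping the whole suite quick on a laptop.

Numerical conventions: trapezoidal integration error is quadratic in scan
spacing (≲ 0.1% at the default grid for σ = 0.012 min peaks, against the
2% recovery tolerance the tests assert); identification ties break first by
|ΔRT|, then by reference-table order; quantiles are type 7; the plasticity
support is taken from the degenerate codon only (never widened by observed
residues); probabilities are clamped to [0, 1] against floating-point
drift in the inclusion–exclusion sum.

## Known limitations

* Quantification is relative; no mg/L calibration, no response factors.
* The identification rule checks primary-ion dominance, not qualifier
  ratios, and cannot distinguish co-eluting isomers — merged peaks (e.g.
  sabinene/myrcene on a fast method) must be encoded as one composite
  reference entry.
* Reads with indels are rejected, not realigned; libraries with more than
  one codon substituted per read are supported by the cleaning rules but
  the shipped simulator plants one codon per read.
* Plate analytics assume every well of a plate shares its controls; there
  is no mixed-effects modelling of plate effects beyond the per-plate
  median normalization.
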