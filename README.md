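# terpscreen

Screening analytics for degenerate-codon libraries of monoterpene
cyclase/synthase (mTC/S) enzymes assayed in vivo by targeted GC-MS.

Directed evolution of mTC/S enzymes runs into two data-analysis problems.
First, each 96-well culture plate yields one GC-MS run per well, and the
question per well is not "what is in it?" but "how much of each of a few
known monoterpenes is in it, relative to controls on the same plate?"
Second, Sanger reads of the hits carry sequencing noise that must be
separated from the single degenerate-codon substitution the library design
permits. `terpscreen` implements the desk side of such a screen for anyone
running plate-based enzyme-variant libraries:

* **Chromatography** — read per-well runs (mzXML via `mzR`, or a plain
  `scan_time_min / mz / intensity` TSV), pick peaks on the total ion
  chromatogram (local maxima with prominence and width filters,
  valley-to-valley bounds), identify them by retention time plus dominant
  primary ion, integrate by the trapezoidal rule, and normalize each
  compound's area to the internal-standard area of the same well.
  Analytes co-eluting with the extraction solvent are masked, never
  quantified.
* **Screen analytics** — per-compound background thresholds as the mean
  normalized signal of solvent-only control wells; a well is *active* when
  at least one targeted compound is strictly above threshold; fold change
  of each well over the median of the plate's parent-enzyme control wells;
  per-library median/quartile summaries.
* **Variant sequencing** — IUPAC degenerate-codon expansion, ungapped
  anchoring of reads on the template (both strands), rule-based cleaning
  (N repair, off-target reversion, whole-codon reversion of
  non-degenerate target codons, template fill of short reads), variant
  calling (`C335A`-style keys, synonymous and low-confidence flags) and
  unique-variant collapse.
* **Sequence–function metrics** — relative product profiles; Euclidean
  distance *d*(*p*, *q*) = √Σ<sub>c</sub>(p<sub>c</sub> − q<sub>c</sub>)²
  between a variant's product fractions and the parent's (0 = identical
  distribution); per-position plasticity score
  Σ<sub>a</sub> min(f<sub>a</sub>, 1/K), the histogram intersection
  between the observed mutant-residue distribution f over the K residues
  the degenerate codon encodes and the uniform distribution (0 = no
  mutants observed, 1 = perfectly uniform); amino-acid occurrence tables;
  and library coverage probability 1 − ((K−1)/K)<sup>n</sup> for n
  colonies over K codons.
* **Simulation** — generators for chromatograms, whole plates and Sanger
  reads with planted ground truth, so every stage of the pipeline is
  testable without instrument data.

## Worked example

```r
library(terpscreen)

# The NBT degenerate codon: 12 codons encoding 11 residues (Ser twice)
exp <- expand_degenerate_codon("NBT")
length(exp$codons)   # 12
length(exp$residues) # 11

# Screening 40 colonies of a 12-codon library: is each codon represented?
cov <- coverage_probability(n_colonies = 40, n_codons = 12)
round(cov$per_variant, 4)  # 0.9692  -- each given codon, p > 0.95
round(cov$all_variants, 4) # 0.6732  -- all 12 codons at once

# One synthetic well: plant two compounds, recover them normalized to the
# internal standard (planted areas 3000 and 1500; IS area 10000)
cfg  <- sim_config(seed = 42)
sim  <- simulate_chromatogram(c("alpha-pinene" = 3000, "limonene" = 1500), cfg)
well <- process_well(sim$chromatogram, default_compound_table())
well
#> <well_result> A1 (sample, ok)
#> sabinene/myrcene     alpha-pinene      beta-pinene         limonene
#>             0.00             0.30             0.00             0.15
#>         linalool         geraniol
#>               NA               NA

# How far has a variant's product profile moved from the parent enzyme's?
parent  <- relative_profile(c("alpha-pinene" = 84, "beta-pinene" = 9,
                              "geraniol" = 3, "myrcene" = 2, "limonene" = 1))
variant <- relative_profile(c("alpha-pinene" = 30, "beta-pinene" = 5,
                              "geraniol" = 40, "myrcene" = 5, "limonene" = 20))
round(euclidean_distance(variant, parent), 3)  # 0.69
```

The recovered normalized areas are exactly the planted area ratios
(3000/10000 and 1500/10000); the masked compounds (linalool, geraniol)
are `NA` because they co-elute with the dodecane solvent peak. The
distance 0.69 quantifies a profile shifted from a pinene-dominated to a
geraniol-dominated mixture (0 means identical product distributions;
two fully disjoint single-product profiles give √2).

A command-line front end over the same functions lives in
`inst/cli/terpscreen.R` (subcommands `simulate`, `call`, `summarize`,
`score`).

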