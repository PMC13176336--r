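---
title: "Models and methods behind tuskDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tuskDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuskDNA)
```

`tuskDNA` implements the dry-lab side of ancient-DNA screening of
worked mammoth ivory: per-library recovery metrics, mitogenome consensus
calling, read-ratio genetic sexing, and the small-sample statistics that
compare tusk tissues and sex ratios. This vignette explains the models,
the defaults and the design choices; the README shows the user-facing
workflow.

## The simulated library model

Real screening data for this problem are partial-UDG, 75-cycle
single-end libraries from Paleolithic ivory. `simulate_library()`
emulates their statistical structure:

* **Endogenous content.** Each sequenced read is endogenous with a fixed
  per-sample probability. Observed ivory libraries span roughly
  0.005–20 % endogenous DNA, and the simulator's per-sample
  `endogenous_fraction` covers that range; the default for a generic
  dentin library is 2 %. Non-endogenous (microbial) reads are carried as
  counts only — read mapping is out of scope, so they never receive
  alignments.
* **Fragment lengths** are lognormal with arithmetic mean 55 bp and sd
  15 bp, truncated to [30, 150] bp. The sequencing chemistry (75 cycles,
  single end) bounds observable length from above, and 30 bp is the
  usual mapping-length floor. The source data publish no length
  distribution, so these are the package's own choice of a typical
  ancient-DNA profile, exposed in `simulation_config()`.
* **Terminal deamination.** C→T substitutions are injected at 5'
  molecule termini (mirrored G→A at 3'), with per-position rates whose
  default is 0.10 at position 1 and 0.03 at position 2, zero beyond — the
  shape of a partial-UDG library, where repair removes internal uracils
  and the downstream 2-bp trim exists precisely because damage is
  concentrated in the first two positions. Stored read sequences are in
  reference orientation; both strands' damage channels therefore appear
  as C→T at the left end and G→A at the right end of the aligned
  segment, which is what `damage_profile()` measures per strand.
* **Sex-linked dosage.** Nuclear reads fall on chrX and chr8
  proportionally to length × copy number: one X copy in males, two in
  females, always two of chromosome 8. Chromosome 8 stands in for an
  autosome of similar size to X, the standard comparator when the
  nuclear reference genome comes from a female and has no Y. The
  simulated references draw chrX and chr8 at equal length (within 20 %
  if configured apart).
* **mtDNA capture.** A baseline fraction of endogenous reads (default
  0.001) is mitochondrial; in-solution capture multiplies that on-target
  share by `capture_on_target_multiplier` (capped at probability 1).
  The enrichment-factor metric recovers this multiplier on simulated
  pairs of shotgun/capture libraries.
* **Duplicates.** A configurable fraction (default 10 %) of mapped reads
  are PCR duplicates, emitted as flagged copies of other placements so
  both deduplication modes (placement-key and flag-honoring) are
  exercised.
* **Seeds.** One master seed; per-sample child seeds derive
  deterministically from it (`child_seed()`), making every batch
  bit-reproducible.

What the simulator deliberately does *not* model: mapping error and
mapping-quality filtering, indels, contamination from related species,
reads wrapping the circular mitogenome origin, and qPCR chemistry
(molecule counts are inputs). Passing tests therefore demonstrate the
pipeline arithmetic and its statistical behaviour under the assumed
generative model, not robustness to alignment artifacts in real data.
One visible consequence of non-wrapping reads is a short coverage ramp
at both reference ends, so breadth saturates slightly below 100 % on
short test references.

## Recovery metrics

The six per-library metrics are implemented exactly as defined
(README for formulas). Two points needed a decision:

* **"Total mapped reads" in mean coverage** is ambiguous between pre-
  and post-deduplication counts; the package defaults to deduplicated,
  quality-filtered reads — the count that actually supports consensus
  coverage — and exposes `mapped_mode = "pre_dedup"` for the other
  reading.
* **Undefined states are first-class.** A zero denominator (e.g. the
  enrichment factor of a library with zero shotgun on-target reads)
  yields `NA_real_`, rendered as the literal string `undefined` in
  reports, never silently 0. Screening tables genuinely contain such
  cells.

## Consensus rule and completeness filter

Sites need ≥ 3 non-duplicated reads and a strict majority (> 50 %) after
2-bp terminal trimming; everything else is `N`. The strict inequality
makes 2/2 ties deterministic `N`s — there is no tie-breaking randomness.
Majorities are computed over the four bases only; indels and ambiguity
codes are outside the model. At 0.5× coverage the expected breadth is
the Poisson tail `P(depth ≥ 3 | λ = 0.5) ≈ 1.4 %`, which the test suite
verifies against simulation.

The completeness filter passes samples with breadth strictly above
90 %. The boundary matters: the packaged screening table contains two
libraries at 90.90 % and 90.98 % that belong in the passing set of 12,
so "excluded below 90" is implemented as *pass iff completeness > 90.0*.

## Genetic sexing

The ratio is `(n_x / L_x) / (n_8 / L_8)` (length normalization on by
default; with similar-size chromosomes it is nearly the count ratio) and
its standard error uses delta-method propagation,
`se = ratio · √(1/n_x + 1/n_8)`. The cited screening studies train
confidence bands on large reference panels that are not reproducible
here, so assignment zones are explicit configuration with defaults
male [0.35, 0.65] and female [0.85, 1.15]; a call requires the
2·se-shifted ratio to land inside a zone, and > 100 reads on each
chromosome for eligibility.

The 2·se margin makes calls conservative at shallow depth: near the
eligibility floor a true female (`ratio ≈ 1 ± 0.09` at ~500 reads per
chromosome) frequently fails `ratio − 2·se ≥ 0.85` and stays
unassigned. The test suite's claim of error-free classification is
therefore made at depths of a few thousand reads per chromosome, where
the margin is several standard errors wide; at the floor the rule trades
recall for precision, which is the intended behaviour for archaeological
material.

## Exact tests

The two-tailed binomial and two-sided Fisher tests are authored
in-package by direct enumeration under the "minlike" convention: the
p-value sums the probabilities of all outcomes no more likely than the
observed one, with a `1 + 1e-7` relative tolerance so that
floating-point noise cannot flip an outcome at the boundary. This is the
convention that reproduces the published two-decimal p-values the
package's fixtures carry (0.12, 0.73, 0.13, 0.57, 1). Tests verify both
implementations against an independent brute-force enumeration oracle on
random instances and against `binom.test()` / `fisher.test()`.

The paired t-test and Shapiro–Wilk gate wrap the standard `stats`
implementations. The gate is advisory — reported alongside every paired
result, never blocking — because screening studies report t-tests for
all metrics regardless of the normality check. Paired fold changes are
reported under both estimators (mean of per-pair ratios, ratio of group
means), since a single printed fold value cannot be disambiguated
between them. Reported p-values are rounded half-up at two decimals in
human-facing output (0.125 prints as 0.13) and stored at full precision
in TSVs.

## Pipeline, sizes and determinism

`run_pipeline()` chains simulate → trim/dedup/pileup → metrics →
consensus → sexing → stats and writes TSV/FASTA/JSON artifacts plus a
provenance record (seed, config MD5). The default demonstration run uses
4 substrate pairs at 20 000 raw reads, 8 sexing libraries at 20 000
reads and 3 capture libraries at 40 000 reads on a 10 kb mitochondrial /
50 kb nuclear reference — sizes chosen so a complete run takes seconds
on a laptop while every stage still has enough counts for its
statistics (capture libraries land near 10× mitochondrial coverage,
comfortably above the depth-3 consensus rule). Identical configurations
produce byte-identical outputs.

## Known limitations

* Substitution-only model: no indels, so consensus length always equals
  reference length.
* The paired-substrate power statements hold for the simulated effect
  sizes (fold 30, +10 bp) at 4 pairs; real per-specimen variability may
  be larger than the lognormal pair-level spread assumed.
* The exact tests enumerate outcomes, which is exact but quadratic in
  table totals; they target screening-scale counts (tens), not large
  contingency tables.
* Sexing assumes reads are already restricted to confidently mapped,
  deduplicated placements; cross-mapping between X and autosomes is not
  modelled.
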