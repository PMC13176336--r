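# tuskDNA

Ancient-DNA screening of Upper Paleolithic mammoth ivory produces very
uneven returns: endogenous DNA content spans four orders of magnitude
(roughly 0.005–20 % of sequenced reads), mitogenomes are reconstructed
from a handful of short, deaminated fragments, and key biological
conclusions — which tusk tissue to sample, and whether people collected
ivory from male or female mammoths — rest on small-sample statistics.
`tuskDNA` packages that whole dry-lab analysis as tested, reusable R
code, together with a simulator that generates ancient-ivory sequencing
libraries with the statistical structure the analysis assumes, so every
stage can be validated without touching archived data.

The package is aimed at ancient-DNA analysts who want the screening
arithmetic (recovery metrics, consensus rule, sexing rule, exact tests)
as callable, tested functions rather than one-off spreadsheet formulas.

## What it computes

**Recovery metrics.** For a library with mapped reads `r` (pre-dedup),
merged/filtered reads `m`, unique mapped reads `u` of mean length `L`,
qPCR molecule count `M` (40 µL library), raw reads `R`, input mass `mg`,
extract volumes `V_tot`/`V_used` and target genome length `G`:

- proportion target DNA: `r / m`
- capture enrichment factor: `p_captured / p_shotgun` (undefined when the
  shotgun proportion is 0)
- informative sequences per mg: `M · u / (m · mg)`
- genomic coverage per 50 mg: `(M · (r/m) · L / G) · (V_tot · 50 / (V_used · mg))`
- cost-effectiveness: `u · L / (R · mg) · 10⁶` (unique bp per million raw
  reads per mg)
- mean coverage: `mapped · L / G`

**Consensus calling.** After 2-bp terminal trimming and deduplication, a
site is called to its majority base iff depth ≥ 3 non-duplicated reads
and the majority frequency is strictly > 50 %; otherwise `N`.
Completeness (breadth) must strictly exceed 90 % for a mitogenome to
pass.

**Genetic sexing.** With one X copy in males and two in females, the
length-normalized ChrX:Chr8 read-count ratio is ≈ 0.5 (male) or ≈ 1
(female); `se = ratio·√(1/n_x + 1/n_8)`, calls require > 100 reads on
both chromosomes and `ratio ± 2·se` inside the male/female zone.

**Exact statistics.** Minlike two-tailed exact binomial and
enumeration-based two-sided Fisher tests (authored in-package, checked
against brute-force enumeration and the stock R implementations), plus a
paired t-test with an advisory Shapiro–Wilk normality gate and
two-estimator fold differences for the dentin-vs-cementum comparison.

## Worked example

```r
library(tuskDNA)

# headline numbers of the packaged 29-library ivory screening table
analyze_table1()
#> Screening-table analysis
#>   mitogenomes above threshold: 12 (48% of 25 specimens)
#>   ivory sex ratio 3:5 males:females
#>   bone sex ratio 1:6 males:females
#>   combined sex ratio 4:11 males:females
#>   binomial vs 1:1 -- combined p = 0.12, ivory p = 0.73, bone p = 0.13
#>   Fisher ivory vs bone p = 0.57; by period p = 1.00
```

Twelve of 29 libraries (48 % of the 25 specimens) clear the > 90 %
completeness filter; none of the sex ratios differs significantly from
1:1 at these sample sizes, and ivory and bone ratios do not differ from
each other.

A full simulated run — 4 dentin/cementum pairs with a 30× endogenous
fold change and +10 bp cementum fragments, 8 sexing libraries, 3
mtDNA-capture libraries:

```r
res <- run_pipeline(run_config(seed = 1), "demo_run")
res$paired_tests[, c("metric", "t", "p_value", "fold_mean_of_ratios")]
#>               metric        t     p_value fold_mean_of_ratios
#> 1 informative_per_mg 2.201739 0.114984944           30.021291
#> 2   prop_mammoth_dna 2.213143 0.113767716           30.624834
#> 3         avg_length 9.645707 0.002365454            1.152608
#> 4  coverage_per_50mg 2.213220 0.113759453           35.339456
#> 5 cost_effectiveness 2.198186 0.115367448           34.579503
res$passing
#> [1] "CAP001" "CAP002" "CAP003"
```

The mean-of-ratios fold estimates recover the simulated 30× substrate
effect; the length metric shows the +10 bp shift (ratio ≈ 1.15 on a
~65 vs ~55 bp baseline). All three capture libraries yield consensus
sequences above the completeness filter. Two shallow female libraries in
`res$sex_calls` come out `unassigned` — with ~480 reads per chromosome
the 2·se confidence margin does not yet clear the female zone, the
intended conservative behaviour.

`demo_run/` then contains `manifest.tsv`, `metrics.tsv` (undefined
enrichment cells rendered as the literal `undefined`),
`consensus.fasta`, `sex_calls.tsv`, `stats_report.tsv`, the YAML config
and a JSON provenance record (seed + config hash); reruns with the same
config are byte-identical.

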