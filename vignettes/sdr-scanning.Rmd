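---
title: "Locating XY sex-determining regions from pooled and RAD sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating XY sex-determining regions from pooled and RAD sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrscan)
```

## The problem and the model

Many fish have young, homomorphic sex chromosomes: a male-heterogametic
(XX/XY) pair that is cytogenetically indistinguishable and differs only in a
short non-recombining sex-determining region (SDR), often tens to hundreds of
kilobases. Two sequencing signatures reveal such a region without any
pedigree:

1. **Allelic divergence.** At a site where X and Y carry different alleles,
   every male is heterozygous and every female homozygous. In pooled
   sequencing of many males versus many females, the male pool's
   alternate-allele frequency is centred on 0.5 while the female pool is
   fixed. A run of such *male-specific SNVs* marks the SDR.
2. **Hemizygosity.** Sequence present only on the Y is covered at half the
   autosomal depth in males (one copy per diploid genome) and at essentially
   zero depth in females.

`sdrscan` implements both scans on pooled allele counts, a presence/absence
screen for RAD markers, and the 2×2 chi-square statistics used to validate
candidate variants with genotyping assays on sexed individuals.

## Site classification and its thresholds

For each pool, allele frequencies are computed from the A/C/G/T read counts
only (N and deletion counts never enter the denominator). With defaults in
`scan_params()`:

* `min_depth = 10` reads per pool — below this a pooled frequency is too
  noisy to call either state; the site is excluded rather than classified.
* heterozygous: minor-allele frequency within `0.5 ± het_delta`
  (`het_delta = 0.1`). At 40× this keeps ~85% of true X/Y sites
  (binomial(40, 0.5)/40 in [0.4, 0.6]) while rejecting skewed background
  sites.
* homozygous: major-allele frequency `≥ hom_min_major` (`0.98`). At depths
  up to 50 this tolerates no more than one non-major read, so a female pool
  carrying any real alternate allele fails, but a single sequencing error
  does not always destroy a true site at lower depth.

These two bands make misclassification of shared polymorphism essentially
impossible: calling a site male-specific requires the male pool to sit in the
heterozygous band while the female pool — sampling the *same* population
frequency — is fixed, a combination with negligible binomial probability at
double-digit depths. Across 100 simulated 6-Mb genomes without any SDR, the
classifier produced zero sex-specific calls.

## Windows, region calls and their defaults

`window_scan()` places windows of `window_size = 5000` bp every
`output_resolution = 1000` bp (half-open intervals, 0-based internally;
reports are 1-based inclusive and say so in their headers). Each SNV is
therefore counted in `window_size / output_resolution` overlapping windows;
`manhattan_bins()` provides the non-overlapping 50-kb summary used for
genome-wide plots, where totals are conserved exactly.

`call_sdr()` merges qualifying windows into regions. Because background
misclassification is effectively zero (above), the evidence threshold per
window can be a single sex-specific SNV (`min_count = 1`); false regions are
controlled instead by the support requirement `min_windows = 10` (at least
ten qualifying windows, i.e. at least two SNVs more than one window apart).
`max_gap = 5` — one window-length of steps — prevents a single sparse 5-kb
stretch from splitting an otherwise contiguous region. A stricter
`min_count` is appropriate when the pools are unbalanced or error rates are
high; the parameters are exposed for that reason. With the defaults, on
simulated 100-kb SDRs at one X/Y-divergent site per kb and 40× pools, the
top-ranked call overlapped the true SDR in 20/20 seeds with called lengths of
103–108 kb (the ~5-kb excess is the window size added at each boundary), and
100 SDR-free genomes produced no call at all. Overlapping candidate calls are
ranked by total SNV count with ties to the leftmost start.

`coverage_regions()` flags Y-limited insertions: windows where female depth
is at most `f_max_frac = 0.1` of the genome-median female depth while male
depth sits within `m_range = c(0.35, 0.65)` of the genome-median male depth
(haploid expectation 0.5, with slack for Poisson noise and window edges).
Depth tracks average over *all* recorded sites, which is why the simulator
emits a dense monomorphic depth record every kb — coverage inference should
not depend on SNV density.

## What the simulator emulates — and what it does not

`simulate_pools()` draws, per chromosome: background polymorphic sites at
`background_snp_rate` per bp whose population frequency comes from a
symmetric Beta(0.7, 0.7) shared by both sexes (realistic non-sex-specific
heterozygosity the classifier must ignore); X/Y-divergent sites at
`xy_divergent_rate` per bp inside the SDR, where the male pool samples the Y
alternate at frequency 0.5 and females are fixed; Poisson(`pool_depth`)
depths, halved for males and zeroed for females inside the Y insertion; and
independent per-read miscalls at `seq_error_rate` to a uniform other base.
There is no recombination inside the SDR: males are modelled as one X plus
one Y haplotype throughout.

Defaults are the study conditions the analyses are designed around: 40×
pools, one divergent site per kb, error 1e-3, 35 males / 34 females, a
10,000-marker RAD panel with one male-limited marker. Two values are not
dictated by any observation and were fixed once as plausible for a wild
percid population: `background_snp_rate = 1e-3` (of the order of fish
genome-wide heterozygosity) and `rad_dropout_rate = 0.05`; both are exposed
in `sim_params()`. The male/female cohort of 35/34 reflects a dataset in
which one of 35 sequenced females was dropped before analysis; the
discrepancy is inherited deliberately and documented rather than resolved.

The generator does **not** emulate read-level artefacts: mapping ambiguity,
MAPQ filtering, indel realignment, GC-dependent coverage, linked paralogs, or
batch differences between pools. Passing tests therefore demonstrate that the
statistics recover the signals they define under sampling noise — not that
the pipeline is robust to alignment artefacts in real data, where repeat
regions routinely mimic coverage signatures.

## Chi-square conventions

Two related but distinct tests are used deliberately:

* The **RAD tile screen** (`significant_cells()`) uses the uncorrected
  Pearson statistic on `[[m, n_males − m], [f, n_females − f]]` per tile
  cell, Bonferroni-corrected over the number of non-empty cells. Markers
  sharing a cell share a p-value, so correcting over cells rather than over
  markers is the natural family; the all-absent cell (0, 0) carries no
  information at the chosen depth and is excluded from both testing and the
  denominator. Cells with a zero column margin (e.g. markers present in
  everyone) have an undefined statistic and are never flagged.
* The **assay linkage tests** (`yates_chi2()`, `genotype_linkage()`,
  `marker_presence_test()`) apply Yates' continuity correction, with each
  cell's `|O − E| − 0.5` clamped at zero so near-independent tables cannot
  accumulate negative contributions. Degenerate margins raise an error
  rather than returning a silently meaningless value; a computable but tiny
  table (such as 1/1 vs 0/1) is reported with a small-sample note.

For genotyping assays, **uncalled genotypes are excluded from the 2×2
table** — the test is about called genotypes, and only this convention
reproduces published assay p-values from their printed counts. The two
report percentages use different denominators on purpose: `%N`
(`pct_genotyped`) divides the assayed total (Ho+He+U) by the recruited
cohort size, and `%As` (`pct_assigned`) divides correct assignments
(heterozygous males plus homozygous females) by the assayed total. Both
conventions were verified against all printed values before being frozen.
P-values below 2.22e-16 are formatted as "< 2.2e-16" while the numeric field
keeps the computed value.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; sync files and TSV reports
  are 1-based (inclusive for intervals) and state the convention in comment
  headers; BED exports are 0-based half-open per the BED standard.
* Determinism: every generator takes its seed from `sim_params()` and
  restores the caller's RNG state; identical seed and parameters give
  byte-identical files. The pipeline manifest records parameters and MD5
  checksums keyed by file name (no timestamps), so reruns can be diffed.
* Windows with no recorded sites report zero SNV counts and `NA` depth —
  zero depth and no data are different states.
* Problem sizes used by the test suite and the acceptance script (3 × 2-Mb
  chromosomes, 20 seeds, 200 null replicates, 10,000 RAD markers) were
  chosen so the full battery completes in about a minute while keeping
  binomial confidence bands narrow enough for 3-standard-error checks.

## Known limitations

* The scan assumes one male pool and one female pool; replicated pools,
  unequal pool sizes, or allele-frequency-difference statistics (F~ST~-style
  scans) are out of scope.
* Region boundaries are window-resolution objects; called lengths
  systematically exceed the true differentiated interval by up to one window
  at each end.
* The RAD screen tests presence/absence only; it cannot detect sex linkage
  expressed as depth differences above the threshold, and markers are not
  mapped to the genome.
* Yates correction is conservative for very small tables; `ns` outcomes on a
  handful of individuals should be treated as uninformative rather than as
  evidence of no linkage.
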