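# sdrscan

Discovery and validation of sex-determining regions (SDRs) in species with
XX/XY sex chromosomes, from three kinds of population-sequencing summaries:

* **Pool-Seq scan** — from per-site allele counts of a male pool and a female
  pool, classify *sex-specific SNVs* (sites heterozygous in one sex's pool and
  homozygous in the other's), build sliding-window density and coverage
  tracks, call SNV-dense candidate SDRs, and detect Y-limited (hemizygous)
  insertions from the male-half / female-zero coverage signature.
* **RAD-seq presence/absence screen** — from a marker-by-individual read-depth
  matrix and phenotypic sexes, build the tile matrix counting markers present
  in exactly *m* males and *f* females, and flag sex-associated cells with a
  Bonferroni-corrected chi-square test.
* **Genotyping-assay linkage statistics** — Pearson's chi-square with Yates'
  continuity correction on 2×2 sex-by-genotype tables, with the reporting
  conventions of KASPar-style assay tables (%N genotyped, %As correctly
  assigned, i.e. heterozygous males and homozygous females).

A seeded simulator of XY populations (`simulate_pools()`, `simulate_rad()`,
`simulate_genotype_table()`) generates inputs with exactly the statistical
structure these analyses assume — X/Y-divergent sites with male-pool
alternate-allele frequency 0.5, shared background polymorphism, Poisson read
depths, hemizygous insertions, marker dropout and genotyping noise — so the
whole pipeline is testable end to end without external data.

## The statistics

At an X/Y-differentiated site, every male carries one X and one Y allele, so
the male pool's alternate-allele frequency is ~0.5 while the female pool is
fixed. A site is called **male-specific** when the male pool's minor-allele
frequency lies in 0.5 ± `het_delta` and the female pool's major-allele
frequency is ≥ `hom_min_major` (defaults 0.1 and 0.98, A/C/G/T reads only,
both pools ≥ `min_depth` = 10). Windows of 5 kb every 1 kb accumulate these
calls; maximal qualifying runs become region calls.

For a 2×2 table with cell counts *O* and margin-derived expectations *E*, the
Yates-corrected statistic is

    chi² = Σ (max(|O − E| − 0.5, 0))² / E ,   p = P(χ²₁ ≥ chi²)

Uncalled genotypes are excluded from the table. The RAD screen uses the
uncorrected Pearson statistic per tile cell, with Bonferroni correction over
the non-empty cells.

## Worked example

```r
library(sdrscan)
layout <- example_layout()                      # 3 x 2 Mb; 100-kb SDR on chr2
sites  <- simulate_pools(layout, sim_params(seed = 1))
track  <- window_scan(sites, scan_params(), chrom_lengths = layout)
call_sdr(track)[1, ]
#>     chrom  start     end n_windows peak_density total_snvs        kind
#> 1:   chr2 946000 1054000       103           10        430 allelic_sdr
annotate_region(call_sdr(track)[1, ], layout$genes)
#> [1] "c18h1orf198" "cx32.2" "gja13.2" "cx32.7" "hsdl1" "tbc1d32"
coverage_regions(track)[1, ]
#>     chrom start     end n_windows mean_depth_m mean_depth_f ...
#> 1:   chr3 1e+06 1053000        49     20.67469            0 ...
```

The top SNV-dense call spans 108 kb around the simulated 100-kb SDR on chr2
and contains the six genes placed inside it; the coverage caller recovers the
53-kb Y-limited insertion on chr3 with ~20× male (haploid) and 0× female
depth at the 40× design depth.

Linkage statistics reproduce published assay tables from their printed
counts:

```r
genotype_linkage(genotype_counts("SNV2", 8, 37, 3, 34, 2, 12), cohort_size = 96)
#> linkage_result: chi2 = 44.07, p = 3.175e-11
#>   % genotyped = 100.0, % assigned = 74.0
```

A thin command-line front end over the same functions is installed at
`system.file("cli/sdrscan.R", package = "sdrscan")` with subcommands
`simulate`, `poolscan`, `radscan`, `linktest` and `run` (full pipeline from a
key-value config; see `?run_pipeline`).

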